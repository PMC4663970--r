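# End-to-end workflows over a single configuration object: simulate the
# ensemble, fit the model hierarchy, run the glider benchmark and the
# lasso scan. Desk-scale defaults; the full-scale ensemble (5e5
# mirror pairs) is reached by raising `n_motions`.

#' Run configuration for the end-to-end workflows
#'
#' Defaults are the canonical constants of the estimation protocol:
#' spatial FWHM 5.7 degrees, receptor spacing 5.1 degrees, photoreceptor
#' time constant 10 ms, correlator time constant 20 ms, 5 ms step, 800 ms
#' clips, velocity SD 90 deg/s.
#'
#' @param image_params [synth_image_params()] for the synthetic image
#'   source (or supply `images` directly to the runners).
#' @param n_images Number of synthetic images.
#' @param n_motions Number of motion draws (ensemble has twice as many
#'   clips).
#' @param seed Master seed.
#' @param cfg [photoreceptor_config()].
#' @param kernels [make_kernels()].
#' @param velocity_sd Velocity prior SD, deg/s.
#' @param architectures Architectures fitted by [run_fit()].
#' @param n_splits Cross-validation divisions.
#' @param protocol [glider_protocol()] used by [run_glider()].
#' @return A list of class `emd_config`.
#' @export
emd_config <- function(image_params = synth_image_params(),
                       n_images = 200L, n_motions = 2000L, seed = 1L,
                       cfg = photoreceptor_config(),
                       kernels = make_kernels(dt = cfg$dt),
                       velocity_sd = 90,
                       architectures = c("hrc", "quadrant", "poly2",
                                         "poly4", "poly6"),
                       n_splits = 20L, protocol = glider_protocol()) {
  structure(list(image_params = image_params, n_images = n_images,
                 n_motions = n_motions, seed = as.integer(seed), cfg = cfg,
                 kernels = kernels, velocity_sd = velocity_sd,
                 architectures = architectures, n_splits = n_splits,
                 protocol = protocol),
            class = "emd_config")
}

#' Simulate the naturalistic motion ensemble of a configuration
#'
#' Generates the synthetic image set and builds the mirror-symmetrized
#' ensemble. Deterministic for a fixed configuration seed.
#'
#' @param config An [emd_config()].
#' @param images Optional pre-built image tibble (overrides the synthetic
#'   source).
#' @return An [`emd_ensemble`][build_ensemble].
#' @export
run_simulate <- function(config, images = NULL) {
  if (is.null(images)) {
    ip <- config$image_params
    ip$seed <- ip$seed + config$seed # tie image stream to the master seed
    images <- synth_image_set(ip, config$n_images)
  }
  build_ensemble(images, config$n_motions, seed = config$seed,
                 cfg = config$cfg, velocity_sd = config$velocity_sd)
}

#' Fit the model hierarchy on an ensemble
#'
#' Fits every architecture in the configuration on the same channel
#' readouts and cross-validation divisions, and returns the accuracy
#' table. Training accuracy is checked for monotonicity along the nested
#' hierarchy hrc -> quadrant -> poly4 -> poly6 (warning on violation).
#'
#' @param config An [emd_config()].
#' @param ensemble An ensemble from [run_simulate()].
#' @return A tibble of class `emd_accuracy` with one row per
#'   architecture (`architecture`, `n_predictors`, `r_train`, `r_test`,
#'   `accuracy_sd`, `mse_test`); the fitted `emd_fit` objects are
#'   attached as attribute `"fits"`.
#' @export
run_fit <- function(config, ensemble) {
  channels <- ensemble_channels(ensemble, config$kernels)
  fits <- lapply(config$architectures, function(a) {
    fit_estimator(channels, a, n_splits = config$n_splits,
                  seed = config$seed)
  })
  names(fits) <- config$architectures
  out <- dplyr::bind_rows(lapply(fits, glance))
  out <- dplyr::bind_cols(
    tibble::tibble(architecture = config$architectures), out)
  nested <- intersect(c("hrc", "quadrant", "poly4", "poly6"),
                      config$architectures)
  if (length(nested) > 1L) {
    rtr <- out$r_train[match(nested, out$architecture)]
    if (any(diff(rtr) < -1e-10)) {
      warning("Training accuracy is not monotone along the nested ",
              "hierarchy: ", paste(nested, collapse = " -> "),
              call. = FALSE)
    }
  }
  attr(out, "fits") <- fits
  class(out) <- c("emd_accuracy", class(out))
  out
}

#' Glider benchmark for a set of fitted models
#'
#' @param config An [emd_config()].
#' @param fits Named list of `emd_fit` objects (attribute `"fits"` of a
#'   [run_fit()] table) or a single fit/model.
#' @return A tibble: the [glider_response()] tables stacked with a
#'   `model` column.
#' @export
run_glider <- function(config, fits) {
  if (inherits(fits, "emd_fit")) fits <- list(model = fits)
  if (inherits(fits, "emd_accuracy")) fits <- attr(fits, "fits")
  if (length(fits) == 0L) stop("No fitted models supplied.", call. = FALSE)
  tabs <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    model <- if (inherits(f, "emd_fit")) f$model else f
    tab <- glider_response(model, config$protocol, config$cfg,
                           config$kernels, seed = config$seed + 100L)
    dplyr::bind_cols(tibble::tibble(model = nm), tab)
  })
  dplyr::bind_rows(tabs)
}

#' Lasso predictor-selection scan on an ensemble
#'
#' Runs [lasso_scan()] on the predictors of one architecture (default the
#' six-channel polynomial), using the HRC's test accuracy on the same
#' split as the gain baseline.
#'
#' @param config An [emd_config()].
#' @param ensemble An ensemble from [run_simulate()].
#' @param architecture Architecture whose predictors are scanned.
#' @return An [`emd_lasso`][lasso_scan] tibble.
#' @export
run_lasso <- function(config, ensemble, architecture = "poly6") {
  channels <- ensemble_channels(ensemble, config$kernels)
  X <- predictor_matrix(channels, architecture)
  hrc_fit <- ols_fit(predictor_matrix(channels, "hrc"), channels$velocity,
                     channels$pair_id, n_splits = 1L, seed = config$seed)
  lasso_scan(X, channels$velocity, pair_id = channels$pair_id,
             seed = config$seed, baseline_r = hrc_fit$splits$r_test[1L])
}
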