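# Plain-text serialization: model parameter files as JSON (round-trip
# exact via full-precision doubles), fit/lasso results as JSON + CSV.

#' Write and read model parameter files
#'
#' Models are stored as JSON with the architecture tag, receptor
#' assignment, exponent table (for polynomial models), weights, and
#' output scale; the round trip is exact.
#'
#' @param model An [emd_model()].
#' @param path File path (`.json`).
#' @return `read_model()` returns the reconstructed `emd_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "emd_model"))
  if (model$architecture == "linear") {
    stop("Composite 'linear' models have function components and are not ",
         "serializable; fit a named architecture instead.", call. = FALSE)
  }
  # weights and scale are written as 17-significant-digit decimal strings,
  # which round-trip IEEE doubles exactly
  payload <- list(
    architecture = model$architecture,
    weights = sprintf("%.17g", model$weights),
    pair = model$pair,
    receptors = model$receptors,
    variant = model$variant,
    scale = sprintf("%.17g", model$scale)
  )
  if (model$architecture %in% c("poly2", "poly4", "poly6")) {
    arity <- as.integer(sub("poly", "", model$architecture))
    payload$exponents <- poly_exponents(arity)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  emd_model(p$architecture, weights = as.numeric(p$weights), pair = p$pair,
            receptors = p$receptors, variant = p$variant,
            scale = as.numeric(p$scale))
}

#' Write a fit result as JSON plus a CSV weight table
#'
#' @param fit An [`emd_fit`][ols_fit].
#' @param stem Output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @export
write_fit <- function(fit, stem) {
  stopifnot(inherits(fit, "emd_fit"))
  jsonlite::write_json(
    list(architecture = fit$architecture %||% NA,
         r_train = fit$r_train, r_test = fit$r_test,
         mse_test = fit$mse_test, scale = fit$scale,
         accuracy_sd = fit$accuracy_sd, n_splits = fit$n_splits, n = fit$n),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(tidy(fit), paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Write a lasso scan as a CSV table
#'
#' One row per penalty; the support is serialized as a
#' semicolon-separated index list.
#'
#' @param scan An [`emd_lasso`][lasso_scan].
#' @param path Output CSV path.
#' @export
write_lasso <- function(scan, path) {
  d <- dplyr::mutate(scan,
                     support = vapply(.data$support, paste, character(1),
                                      collapse = ";"))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}
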