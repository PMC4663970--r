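# Least-squares fitting of predictor weights with mirror-paired twofold
# cross-validation, optimal output scaling, and lasso predictor selection.

# Solve min ||y - X b||^2 without intercept. Rank-deficient systems get
# the minimum-norm solution (via SVD) with a warning.
ols_solve <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("Predictor matrix is rank deficient; returning the ",
            "minimum-norm solution.", call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    b <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    return(drop(b))
  }
  drop(qr.coef(qr_x, y))
}

# Correlation and spread about zero. The velocity prior is zero-mean and
# the models have no intercept, so all accuracy statistics use moments
# about zero; this makes the MSE-correlation identity exact in-sample.
r_zero <- function(a, b) {
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}
sd_zero <- function(x) sqrt(mean(x^2))

# Split pair ids 50/50; mirror pairs are atomic units of the split.
split_pairs <- function(pair_ids, seed) {
  u <- unique(pair_ids)
  withr::with_seed(as.integer(seed), {
    tr <- sample(u, floor(length(u) / 2))
  })
  list(train = pair_ids %in% tr, test = !(pair_ids %in% tr))
}

#' Optimally scale a raw estimator output
#'
#' Scales raw estimates by \eqn{r \sigma_v / \sigma_R} (with `r` the
#' correlation between raw output and velocity), the gain that minimizes
#' the mean squared error. All moments are taken about zero (the velocity
#' prior is zero-mean and the estimators have no constant term), so the
#' scaled estimator satisfies \eqn{MSE = \sigma_v^2 (1 - r^2)} exactly on
#' the sample used for scaling.
#'
#' @param raw Raw estimator outputs.
#' @param v True velocities (zero-mean prior).
#' @return The scaled estimates, with attributes `scale` and `r`. A
#'   degenerate (all-zero) raw output returns zeros with a warning.
#' @export
scale_output <- function(raw, v) {
  s_r <- sd_zero(raw)
  if (!is.finite(s_r) || s_r == 0) {
    warning("Raw estimator output has zero spread; returning the null ",
            "estimator.", call. = FALSE)
    out <- rep(0, length(raw))
    attributes(out) <- c(attributes(out), list(scale = 0, r = 0))
    return(out)
  }
  r <- r_zero(raw, v)
  sc <- r * sd_zero(v) / s_r
  out <- sc * raw
  attr(out, "scale") <- sc
  attr(out, "r") <- r
  out
}

#' Fit predictor weights by cross-validated least squares
#'
#' Minimizes the mean squared error between a linear combination of
#' predictors and the true velocity, with twofold cross-validation in
#' which mirror pairs are atomic (both members always fall in the same
#' fold). The reported accuracy is the correlation coefficient on the
#' held-out fold, averaged over `n_splits` random divisions; its standard
#' deviation across splits is the accuracy SD. The returned weights and
#' output scale come from the first split.
#'
#' @param X Numeric predictor matrix, one row per clip.
#' @param v Velocity of each clip (deg/s).
#' @param pair_id Mirror-pair identifier of each clip.
#' @param n_splits Number of random 50/50 divisions (default 20).
#' @param seed Seed for the divisions.
#' @return An object of class `emd_fit`: weights, `r_train`, `r_test`,
#'   `mse_test` (of the optimally scaled estimator), `scale`,
#'   `accuracy_sd`, `n_splits`, and a per-split tibble `splits`.
#' @export
ols_fit <- function(X, v, pair_id = seq_along(v), n_splits = 20L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(v), length(pair_id) == length(v))
  res <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- split_pairs(pair_id, seed + s - 1L)
    b <- ols_solve(X[sp$train, , drop = FALSE], v[sp$train])
    raw_tr <- drop(X[sp$train, , drop = FALSE] %*% b)
    raw_te <- drop(X[sp$test, , drop = FALSE] %*% b)
    sc_tr <- scale_output(raw_tr, v[sp$train])
    sc <- attr(sc_tr, "scale")
    r_tr <- attr(sc_tr, "r")
    # test MSE of the optimally scaled test output, so the
    # MSE-correlation identity holds on the held-out fold too
    sc_te <- scale_output(raw_te, v[sp$test])
    r_te <- attr(sc_te, "r")
    mse_te <- mean((v[sp$test] - sc_te)^2)
    res[[s]] <- list(b = b, scale = sc, r_train = r_tr, r_test = r_te,
                     mse_test = mse_te)
  }
  splits <- tibble::tibble(
    split = seq_len(n_splits),
    r_train = vapply(res, `[[`, numeric(1), "r_train"),
    r_test = vapply(res, `[[`, numeric(1), "r_test"),
    mse_test = vapply(res, `[[`, numeric(1), "mse_test")
  )
  first <- res[[1L]]
  w <- first$b
  names(w) <- colnames(X)
  structure(list(weights = w, scale = first$scale,
                 r_train = mean(splits$r_train),
                 r_test = mean(splits$r_test),
                 mse_test = mean(splits$mse_test),
                 accuracy_sd = stats::sd(splits$r_test),
                 n_splits = n_splits, n = length(v),
                 sigma_v = sd_zero(v), splits = splits),
            class = "emd_fit")
}

#' @export
print.emd_fit <- function(x, ...) {
  cat(sprintf(
    "<emd_fit> %d predictors, n = %d\n  r_test = %.4f (SD %.4f over %d splits), mse_test = %.1f\n",
    length(x$weights), x$n, x$r_test, x$accuracy_sd %||% NA_real_,
    x$n_splits, x$mse_test))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.emd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$weights) %||% paste0("x", seq_along(x$weights)),
                 estimate = unname(x$weights))
}

#' @export
glance.emd_fit <- function(x, ...) {
  tibble::tibble(r_train = x$r_train, r_test = x$r_test,
                 mse_test = x$mse_test, accuracy_sd = x$accuracy_sd,
                 n_splits = x$n_splits, n_predictors = length(x$weights),
                 n = x$n)
}

#' Lasso scan over predictor subsets with OLS refit
#'
#' Sweeps an L1 penalty over z-scored predictors, extracts the support
#' (set of selected predictors) at each penalty, refits the support by
#' ordinary least squares on the training fold (no penalty), and records
#' the held-out correlation. This produces the support-size versus
#' accuracy curve used to identify small predictor subsets that retain
#' most of the full model's accuracy.
#'
#' @inheritParams ols_fit
#' @param penalty_grid Decreasing penalty values; `NULL` uses the
#'   glmnet-chosen logarithmic path of `n_penalties` values.
#' @param n_penalties Length of the automatic path.
#' @param baseline_r Optional reference accuracy (e.g. the HRC's test r)
#'   used for `gain_fraction = (r - baseline_r) / (r_full - baseline_r)`.
#' @return A tibble of class `emd_lasso` with one row per penalty:
#'   `penalty`, `n_support`, `support` (list of integer predictor
#'   indices), `r_test`, and `gain_fraction`. The full-support OLS
#'   accuracy is attached as attribute `"r_full"`.
#' @export
lasso_scan <- function(X, v, penalty_grid = NULL, pair_id = seq_along(v),
                       seed = 1L, n_penalties = 50L, baseline_r = NULL) {
  X <- as.matrix(X)
  if (!is.null(penalty_grid) && length(penalty_grid) == 0L) {
    stop("Empty penalty grid.", call. = FALSE)
  }
  sp <- split_pairs(pair_id, seed)
  Xtr <- X[sp$train, , drop = FALSE]
  vtr <- v[sp$train]
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
  fit <- glmnet::glmnet(Z, vtr, alpha = 1, intercept = FALSE,
                        standardize = FALSE, lambda = penalty_grid,
                        nlambda = n_penalties)
  lambdas <- fit$lambda
  refit_one <- function(support) {
    if (length(support) == 0L) {
      return(list(r = 0, w = numeric(0)))
    }
    b <- ols_solve(Xtr[, support, drop = FALSE], vtr)
    raw_te <- drop(X[sp$test, support, drop = FALSE] %*% b)
    list(r = r_zero(raw_te, v[sp$test]), w = b)
  }
  full <- refit_one(seq_len(ncol(X)))
  rows <- lapply(seq_along(lambdas), function(k) {
    beta <- fit$beta[, k]
    support <- which(beta != 0)
    rf <- refit_one(support)
    tibble::tibble(penalty = lambdas[k], n_support = length(support),
                   support = list(unname(support)), r_test = rf$r)
  })
  out <- dplyr::bind_rows(rows)
  out$gain_fraction <- if (is.null(baseline_r)) NA_real_ else {
    (out$r_test - baseline_r) / (full$r - baseline_r)
  }
  attr(out, "r_full") <- full$r
  attr(out, "baseline_r") <- baseline_r
  class(out) <- c("emd_lasso", class(out))
  out
}

#' Fit a named architecture to ensemble channel readouts
#'
#' High-level wrapper: builds the predictor matrix of an architecture
#' from channel readouts, runs [ols_fit()], and returns both the fit and
#' the ready-to-evaluate [emd_model()] (weights plus optimal output
#' scale). Architecture tags: `"hrc"`, `"hrc_conv3pt"` (HRC plus
#' converging 3-point correlator), `"conv3pt"`, `"quadrant"`, `"poly2"`,
#' `"poly4"`, `"poly6"`.
#'
#' @param channels Channel readout tibble from [ensemble_channels()]
#'   (must contain `velocity` and `pair_id`).
#' @param architecture Architecture tag.
#' @param variant Converging 3-point variant where relevant.
#' @param pair,receptors Receptor assignment.
#' @inheritParams ols_fit
#' @return An `emd_fit` with the fitted `emd_model` in `$model` and the
#'   architecture tag in `$architecture`.
#' @export
fit_estimator <- function(channels, architecture, variant = "two_site",
                          pair = c(1L, 2L), receptors = 1:3,
                          n_splits = 20L, seed = 1L) {
  X <- predictor_matrix(channels, architecture, variant = variant,
                        pair = pair, receptors = receptors)
  fit <- ols_fit(X, channels$velocity, channels$pair_id,
                 n_splits = n_splits, seed = seed)
  fit$architecture <- architecture
  fit$model <- architecture_model(architecture, fit$weights, fit$scale,
                                  variant = variant, pair = pair,
                                  receptors = receptors)
  fit
}

#' Predictor matrix of a named architecture
#'
#' @inheritParams fit_estimator
#' @return Numeric matrix with one column per predictor.
#' @export
predictor_matrix <- function(channels, architecture, variant = "two_site",
                             pair = c(1L, 2L), receptors = 1:3) {
  ch <- as.list(channels)
  switch(architecture,
    hrc = cbind(hrc = hrc(ch, pair)),
    conv3pt = cbind(conv3pt = converging_3pt(ch, variant, pair)),
    hrc_conv3pt = cbind(hrc = hrc(ch, pair),
                        conv3pt = converging_3pt(ch, variant, pair)),
    quadrant = {
      q <- quadrant_signals(ch, pair)
      cbind(pp = q$pp, pm = q$pm, mp = q$mp, mm = q$mm)
    },
    classes = {
      cl <- correlation_classes(quadrant_signals(ch, pair))
      cbind(even2 = cl$even2, odd = cl$odd, oddstar = cl$oddstar,
            even_gt2 = cl$even_gt2)
    },
    poly2 = poly_features(ch, 2L, pair = pair),
    poly4 = poly_features(ch, 4L, pair = pair),
    poly6 = poly_features(ch, 6L, receptors = receptors),
    stop(sprintf("Unknown architecture '%s'.", architecture), call. = FALSE)
  )
}

# Wrap fitted weights in the matching emd_model.
architecture_model <- function(architecture, weights, scale,
                               variant = "two_site", pair = c(1L, 2L),
                               receptors = 1:3) {
  switch(architecture,
    hrc = emd_model("hrc", weights, pair = pair, scale = scale),
    conv3pt = emd_model("conv3pt", weights, pair = pair, variant = variant,
                        scale = scale),
    hrc_conv3pt = emd_model("linear", weights, scale = scale, components =
      list(function(ch) hrc(ch, pair),
           function(ch) converging_3pt(ch, variant, pair))),
    quadrant = emd_model("quadrant", weights, pair = pair, scale = scale),
    classes = emd_model("linear", weights, scale = scale, components =
      lapply(c("even2", "odd", "oddstar", "even_gt2"), function(nm) {
        force(nm)
        function(ch) correlation_classes(quadrant_signals(ch, pair))[[nm]]
      })),
    poly2 = emd_model("poly2", weights, pair = pair, scale = scale),
    poly4 = emd_model("poly4", weights, pair = pair, scale = scale),
    poly6 = emd_model("poly6", receptors = receptors, weights = weights,
                      scale = scale)
  )
}
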