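# Statistical characterizations: moments of signal pools and spatial
# covariance of image ensembles. Population (biased) estimators
# throughout, matching the large-sample regime these summaries serve.

#' Kurtosis (standardized fourth central moment)
#'
#' \eqn{\mu_4 / \sigma^4} with population normalization and no excess
#' shift: the Gaussian scores 3, the uniform 1.8, and the symmetric
#' Bernoulli 1 -- the minimum of any distribution.
#'
#' @param x Numeric sample, length >= 4, nonzero variance.
#' @return A single number >= 1.
#' @export
kurtosis <- function(x) {
  stopifnot(length(x) >= 4L)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("Zero variance: kurtosis is undefined.", call. = FALSE)
  mean((x - m)^4) / v^2
}

#' Skewness (standardized third central moment)
#'
#' @inheritParams kurtosis
#' @export
skewness <- function(x) {
  stopifnot(length(x) >= 3L)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("Zero variance: skewness is undefined.", call. = FALSE)
  mean((x - m)^3) / v^1.5
}

#' Moment summary of a sample
#'
#' @inheritParams kurtosis
#' @return A one-row tibble: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `n`.
#' @export
moment_report <- function(x) {
  tibble::tibble(mean = mean(x), variance = mean((x - mean(x))^2),
                 skewness = skewness(x), kurtosis = kurtosis(x),
                 n = length(x))
}

#' Spatial covariance of a panoramic image ensemble
#'
#' Ensemble- and position-averaged product of mean-removed contrasts at
#' two points separated horizontally by each lag, with periodic wrap.
#' Lag 0 gives the ensemble variance.
#'
#' @param images Tibble with an `image` list-column, or list of
#'   [`emd_image`][synth_image] objects (>= 2 images).
#' @param max_lag Largest separation in degrees (< 180).
#' @return A tibble with columns `lag` (degrees) and `covariance`.
#' @export
spatial_covariance <- function(images, max_lag = 30) {
  img_list <- if (is.data.frame(images)) images$image else images
  if (length(img_list) < 2L) stop("Need at least 2 images.", call. = FALSE)
  if (max_lag >= 180) {
    stop("`max_lag` must be below 180 degrees (aliasing under reflection).",
         call. = FALSE)
  }
  pitch <- img_list[[1L]]$pixel_pitch
  X <- vapply(img_list, function(im) im$contrast,
              numeric(length(img_list[[1L]]$contrast)))
  X <- X - mean(X)
  n <- nrow(X)
  lags <- 0:floor(max_lag / pitch)
  cov <- vapply(lags, function(l) {
    idx <- ((seq_len(n) - 1L + l) %% n) + 1L
    mean(X * X[idx, , drop = FALSE])
  }, numeric(1))
  tibble::tibble(lag = lags * pitch, covariance = cov)
}
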