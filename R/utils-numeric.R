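# Internal numerical primitives shared across modules.

# Discretized Gaussian kernel on a regular grid (degrees), truncated at
# +/- 3 sigma and renormalized to unit sum. `fwhm` and `pitch` in degrees.
gauss_kernel <- function(fwhm, pitch) {
  stopifnot(fwhm > 0, pitch > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma / pitch))
  w <- stats::dnorm(seq(-half, half) * pitch, mean = 0, sd = sigma)
  w / sum(w)
}

# Causal discrete convolution: y[t] = sum_j k[j] * x[t - j + 1], with the
# signal zero-padded before its first sample (zero initial filter state).
# x may be a vector or a matrix (filtered column-wise).
causal_conv <- function(x, k) {
  nk <- length(k)
  if (is.matrix(x)) {
    pad <- rbind(matrix(0, nk - 1L, ncol(x)), x)
    y <- stats::filter(pad, k, method = "convolution", sides = 1L)
    return(as.matrix(y)[nk:(nk + nrow(x) - 1L), , drop = FALSE])
  }
  pad <- c(rep(0, nk - 1L), x)
  y <- stats::filter(pad, k, method = "convolution", sides = 1L)
  as.numeric(y)[nk:(nk + length(x) - 1L)]
}

# Circular (periodic) convolution of a signal with a centered, odd-length
# kernel; used for panoramic spatial blurring.
periodic_conv <- function(x, k) {
  stopifnot(length(k) %% 2L == 1L, length(k) <= length(x))
  as.numeric(stats::filter(x, k, method = "convolution",
                           sides = 2L, circular = TRUE))
}

# Linear interpolation of a periodic signal sampled at pixel centers
# 0, pitch, 2*pitch, ... Positions `xq` in the same (degree) units; the
# signal wraps with period length(b) * pitch.
interp_periodic <- function(b, xq, pitch = 1) {
  n <- length(b)
  u <- (xq / pitch) %% n
  j0 <- floor(u)
  fr <- u - j0
  i0 <- as.integer(j0 %% n) + 1L
  i1 <- as.integer((j0 + 1) %% n) + 1L
  b[i0] * (1 - fr) + b[i1] * fr
}

# Causal exponential kernel exp(-t/tau) on the dt grid, normalized to unit
# sum; support defaults to 8 tau (mass loss < 4e-4 before renormalization).
exp_kernel <- function(tau, dt, support = 8 * tau) {
  stopifnot(tau > 0, dt > 0, dt < tau)
  tt <- seq(0, support, by = dt)
  k <- exp(-tt / tau)
  k / sum(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
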