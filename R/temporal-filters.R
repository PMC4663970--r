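#' Low-pass and high-pass filter kernels of the correlator
#'
#' Builds the discretized temporal kernel pair used by every motion
#' estimator in the package: a low-pass kernel \eqn{f(t) = t e^{-t/\tau}}
#' for \eqn{t \ge 0} and a high-pass kernel \eqn{g(t) = df/dt =
#' (1 - t/\tau) e^{-t/\tau}}. Both are causal and live on the simulation
#' time grid. `f` is scaled to unit discrete sum; `g` is scaled by the same
#' factor and then mean-adjusted so that its discrete sum is exactly zero,
#' which guarantees that constant signals are annihilated. Overall kernel
#' gain is absorbed by the fitted weights downstream, so this normalization
#' only affects numerical conditioning.
#'
#' @param tau Filter time constant in seconds (default 0.020 s).
#' @param dt Time step in seconds (default 0.005 s). Must satisfy `dt < tau`.
#' @param support Kernel support in seconds; must be at least `10 * tau`.
#'
#' @return An object of class `emd_kernels`: a list with elements `f`, `g`
#'   (numeric kernels), `tau`, `dt`, and `support`.
#' @examples
#' k <- make_kernels()
#' which.max(k$f)            # f peaks at t = tau
#' abs(sum(k$g)) < 1e-15     # g annihilates constants
#' @export
make_kernels <- function(tau = 0.020, dt = 0.005, support = 10 * tau) {
  if (dt >= tau) {
    stop("`dt` must be smaller than `tau`: the kernel would be undersampled.",
         call. = FALSE)
  }
  if (support < 10 * tau) {
    stop("`support` must be at least 10 * tau.", call. = FALSE)
  }
  tt <- seq(0, support, by = dt)
  f <- tt * exp(-tt / tau)
  g <- (1 - tt / tau) * exp(-tt / tau)
  sf <- sum(f)
  f <- f / sf
  g <- g / sf
  g <- g - mean(g) # exact discrete zero sum
  structure(list(f = f, g = g, tau = tau, dt = dt, support = support),
            class = "emd_kernels")
}

#' @export
print.emd_kernels <- function(x, ...) {
  cat(sprintf("<emd_kernels> tau = %g s, dt = %g s, %d taps\n",
              x$tau, x$dt, length(x$f)))
  invisible(x)
}

#' Apply the correlator's filter pair to a motion clip
#'
#' Convolves each photoreceptor signal of a clip with the low-pass kernel
#' `f` and the high-pass kernel `g` (causal discrete convolution, zero
#' initial state), producing the channel bank that every estimator
#' consumes. For a 3-receptor clip the channels are, in order,
#' `f1, g1, f2, g2, f3, g3`.
#'
#' @param clip A [motion clip][photoreceptor_response], or any matrix with
#'   one receptor per row on the kernel time grid.
#' @param kernels Kernels from [make_kernels()]; its `dt` must match the
#'   clip's.
#'
#' @return An object of class `emd_bank`: list with `channels` (matrix,
#'   channel-by-time, rownames `f1, g1, ...`), `readout_index` (the final
#'   time point, used as the instantaneous estimate by all models), and
#'   `dt`.
#' @export
filter_bank <- function(clip, kernels = make_kernels()) {
  V <- if (is.matrix(clip)) clip else clip$V
  dt_clip <- if (is.matrix(clip)) kernels$dt else clip$dt
  if (abs(dt_clip - kernels$dt) > 1e-12) {
    stop("Clip and kernels are on different time grids (dt mismatch).",
         call. = FALSE)
  }
  nr <- nrow(V)
  Fc <- causal_conv(t(V), kernels$f) # time x receptor
  Gc <- causal_conv(t(V), kernels$g)
  ch <- matrix(NA_real_, 2L * nr, ncol(V))
  for (i in seq_len(nr)) {
    ch[2L * i - 1L, ] <- Fc[, i]
    ch[2L * i, ] <- Gc[, i]
  }
  rownames(ch) <- as.vector(rbind(paste0("f", seq_len(nr)),
                                  paste0("g", seq_len(nr))))
  structure(list(channels = ch, readout_index = ncol(V), dt = kernels$dt),
            class = "emd_bank")
}

# Readout of a bank at its final time point, as a named numeric vector.
bank_readout <- function(bank) {
  bank$channels[, bank$readout_index]
}
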