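# Independent oracles used by the derived-value tests. These deliberately
# use brute-force formulations, not the package's code paths.

# Dense O(N^2) causal convolution sum.
oracle_causal_conv <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(k)) {
      if (t - j + 1 >= 1) y[t] <- y[t] + k[j] * x[t - j + 1]
    }
  }
  y
}

# Brute-force reflective tiling: concatenate alternately reversed copies
# and crop centered on the original row.
oracle_reflect_tile <- function(row, n_out) {
  L <- length(row)
  reps <- 2 * (ceiling(n_out / L) + 2) + 1
  mid <- (reps + 1) / 2
  ext <- unlist(lapply(seq_len(reps),
                       function(j) if ((j - mid) %% 2 == 0) row else rev(row)))
  center <- (mid - 1) * L + (L + 1) / 2
  start <- as.integer(round(center - n_out / 2 + 0.5))
  ext[start:(start + n_out - 1)]
}

# Brute-force quadrature of the photoreceptor response integral
# V_i(t) = int dt' T(t') int dx M(x - x_i) c(x - v (t - t'))
# on a grid `refine` times finer in both x and t than the simulation
# grid, with continuous-normalized kernels.
oracle_photoreceptor <- function(image, velocity, offset, cfg,
                                 t_eval, receptor, refine = 10) {
  sigma <- cfg$spatial_fwhm / (2 * sqrt(2 * log(2)))
  dx <- image$pixel_pitch / refine
  xs <- seq(0, 360 - dx, by = dx)
  cx <- function(x) { # continuous image: linear interp of the 1-deg pixels
    n <- length(image$contrast)
    u <- (x / image$pixel_pitch) %% n
    j0 <- floor(u); fr <- u - j0
    image$contrast[(j0 %% n) + 1] * (1 - fr) +
      image$contrast[((j0 + 1) %% n) + 1] * fr
  }
  xi <- offset + (receptor - 1) * cfg$spacing
  d <- (xs - xi + 180) %% 360 - 180
  Mw <- exp(-d^2 / (2 * sigma^2))
  Mw <- Mw / sum(Mw)
  dtp <- cfg$dt / refine
  tps <- seq(0, 8 * cfg$temporal_tau, by = dtp)
  Tw <- exp(-tps / cfg$temporal_tau)
  Tw <- Tw / sum(Tw)
  sapply(t_eval, function(t) {
    s_vals <- sapply(tps, function(tp) {
      tau_lag <- t - tp
      if (tau_lag <= 0) return(0) # zero state before clip onset
      sum(Mw * cx(xs - velocity * tau_lag))
    })
    sum(Tw * s_vals)
  })
}

# Random filter-bank readouts (named channel vectors) for identity tests.
random_banks <- function(n, n_receptors = 3, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ch <- stats::rnorm(2 * n_receptors)
      names(ch) <- as.vector(rbind(paste0("f", 1:n_receptors),
                                   paste0("g", 1:n_receptors)))
      ch
    })
  })
}

# Swap of the two receptors a pairwise correlator reads.
mirror_pair <- function(ch) {
  out <- ch
  out[c("f1", "g1", "f2", "g2")] <- ch[c("f2", "g2", "f1", "g1")]
  out
}

# Receptor-order reversal of a named channel vector.
mirror_channels <- function(ch) {
  nr <- length(ch) / 2
  out <- ch
  for (i in seq_len(nr)) {
    out[paste0("f", i)] <- ch[paste0("f", nr - i + 1)]
    out[paste0("g", i)] <- ch[paste0("g", nr - i + 1)]
  }
  out
}
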