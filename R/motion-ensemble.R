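#' Photoreceptor and simulation constants
#'
#' Bundles the optics and discretization constants used throughout:
#' spatial Gaussian acceptance (FWHM 5.7 degrees), causal exponential
#' temporal kernel (10 ms), receptor spacing 5.1 degrees, 3 receptors,
#' 5 ms time step, 800 ms clip duration.
#'
#' @param spatial_fwhm Gaussian acceptance FWHM, degrees.
#' @param temporal_tau Photoreceptor temporal time constant, seconds.
#' @param spacing Angular spacing between adjacent receptors, degrees.
#' @param n_receptors Number of receptors simulated per clip.
#' @param dt Simulation time step, seconds.
#' @param duration Clip duration, seconds; must be an integer multiple of `dt`.
#' @return A list of class `photoreceptor_config`.
#' @export
photoreceptor_config <- function(spatial_fwhm = 5.7, temporal_tau = 0.010,
                                 spacing = 5.1, n_receptors = 3L,
                                 dt = 0.005, duration = 0.800) {
  vals <- c(spatial_fwhm, temporal_tau, spacing, n_receptors, dt, duration)
  if (any(vals <= 0)) stop("All configuration values must be positive.",
                           call. = FALSE)
  if (duration < dt) stop("`duration` must be at least one time step.",
                          call. = FALSE)
  nt <- duration / dt
  if (abs(nt - round(nt)) > 1e-9) {
    stop("`duration` must be an integer multiple of `dt`.", call. = FALSE)
  }
  structure(list(spatial_fwhm = spatial_fwhm, temporal_tau = temporal_tau,
                 spacing = spacing, n_receptors = as.integer(n_receptors),
                 dt = dt, duration = duration, n_steps = as.integer(round(nt))),
            class = "photoreceptor_config")
}

# Spatially blurred panorama: periodic convolution of the 1-degree contrast
# row with the acceptance Gaussian sampled at pixel centers.
blur_panorama <- function(image, cfg) {
  periodic_conv(image$contrast, gauss_kernel(cfg$spatial_fwhm, image$pixel_pitch))
}

#' Photoreceptor responses to rigid translation of a panorama
#'
#' Simulates the linear response of `n_receptors` adjacent photoreceptors
#' to a panoramic contrast image translating rigidly at constant velocity:
#' the image is blurred with the spatial Gaussian, sampled at each
#' receptor's (moving) gaze direction with linear sub-pixel interpolation
#' and periodic wrap, and passed through the causal exponential temporal
#' kernel from zero initial filter state.
#'
#' @param image An [`emd_image`][make_row_image] spanning 360 degrees.
#' @param velocity Constant angular velocity, degrees per second
#'   (positive = rightward).
#' @param offset Initial angular position of the first receptor, degrees.
#' @param cfg A [photoreceptor_config()].
#' @param blurred Optional precomputed [blurred panorama]; internal use.
#' @return A list of class `motion_clip` with elements `V`
#'   (receptor-by-time matrix), `velocity`, `offset`, `dt`, `image_ref`.
#' @export
photoreceptor_response <- function(image, velocity, offset = 0,
                                   cfg = photoreceptor_config(),
                                   blurred = NULL) {
  stopifnot(inherits(image, "emd_image"), is.finite(velocity))
  b <- blurred %||% blur_panorama(image, cfg)
  tt <- cfg$dt * seq_len(cfg$n_steps)
  Tk <- exp_kernel(cfg$temporal_tau, cfg$dt)
  S <- matrix(NA_real_, cfg$n_steps, cfg$n_receptors)
  for (i in seq_len(cfg$n_receptors)) {
    xi <- offset + (i - 1L) * cfg$spacing
    S[, i] <- interp_periodic(b, xi - velocity * tt, image$pixel_pitch)
  }
  V <- t(causal_conv(S, Tk))
  rownames(V) <- paste0("V", seq_len(cfg$n_receptors))
  structure(list(V = V, velocity = velocity, offset = offset, dt = cfg$dt,
                 image_ref = image$source_tag),
            class = "motion_clip")
}

# Mirror partner of a clip: receptor order reversed, velocity negated.
# This is exact by construction (reflected image + inverted velocity +
# matched offset produce exactly the reversed receptor set).
mirror_clip <- function(clip) {
  V <- clip$V[rev(seq_len(nrow(clip$V))), , drop = FALSE]
  rownames(V) <- paste0("V", seq_len(nrow(V)))
  structure(list(V = V, velocity = -clip$velocity, offset = clip$offset,
                 dt = clip$dt, image_ref = paste0(clip$image_ref, "_mirror")),
            class = "motion_clip")
}

#' Photoreceptor responses to an arbitrary space-time movie
#'
#' Generalizes [photoreceptor_response()] to non-rigid stimuli such as
#' glider movies: a space-by-time contrast matrix with a given pixel pitch
#' and frame interval is rendered piecewise-constant in space and time,
#' blurred with the acceptance Gaussian (pixel weights integrated by
#' sub-pixel quadrature), sampled at fixed receptor positions, upsampled
#' to the simulation time step, and passed through the temporal kernel.
#'
#' @param movie Numeric matrix, space (pixels) by time (frames).
#' @param pixel_pitch Pixel size in degrees.
#' @param frame_dt Frame interval in seconds; must be an integer multiple
#'   of `cfg$dt`.
#' @param positions Receptor gaze directions in degrees.
#' @param cfg A [photoreceptor_config()].
#' @param boundary `"periodic"` (default) or `"error"` for positions
#'   outside the movie's angular span.
#' @return Matrix of filtered responses, position-by-time, on the `cfg$dt`
#'   grid (`ncol(movie) * frame_dt / dt` columns).
#' @export
movie_response <- function(movie, pixel_pitch, frame_dt, positions,
                           cfg = photoreceptor_config(),
                           boundary = c("periodic", "error")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(movie), all(is.finite(movie)))
  span <- nrow(movie) * pixel_pitch
  if (boundary == "error" &&
      (any(positions < 0) || any(positions >= span))) {
    stop("Receptor position outside the movie's angular span.", call. = FALSE)
  }
  rep_t <- frame_dt / cfg$dt
  if (abs(rep_t - round(rep_t)) > 1e-9) {
    stop("`frame_dt` must be an integer multiple of `cfg$dt`.", call. = FALSE)
  }
  rep_t <- as.integer(round(rep_t))
  W <- movie_blur_weights(nrow(movie), pixel_pitch, positions, cfg)
  Sf <- W %*% movie                       # position x frame
  S <- Sf[, rep(seq_len(ncol(Sf)), each = rep_t), drop = FALSE]
  Tk <- exp_kernel(cfg$temporal_tau, cfg$dt)
  V <- t(causal_conv(t(S), Tk))
  dimnames(V) <- NULL
  V
}

# Spatial blur weights of movie pixels for each receptor position:
# the Gaussian integrated over each (piecewise-constant) pixel by an
# 11-point sub-pixel quadrature, wrapped periodically, rows renormalized.
movie_blur_weights <- function(n_px, pixel_pitch, positions, cfg) {
  sigma <- cfg$spatial_fwhm / (2 * sqrt(2 * log(2)))
  span <- n_px * pixel_pitch
  nsub <- 11L
  # pixel j is centered at (j-1) * pitch, matching the panorama grid
  sub <- (seq_len(nsub) - 0.5) / nsub - 0.5 # offsets within a pixel, in pixels
  centers_sub <- as.vector(outer(sub, seq_len(n_px) - 1L, `+`)) * pixel_pitch
  W <- matrix(0, length(positions), n_px)
  for (p in seq_along(positions)) {
    d <- (centers_sub - positions[p] + span / 2) %% span - span / 2
    w <- stats::dnorm(d, 0, sigma)
    W[p, ] <- colSums(matrix(w, nrow = nsub))
  }
  W / rowSums(W)
}

#' Build a mirror-symmetrized ensemble of naturalistic motions
#'
#' Draws `n_motions` (image, offset, velocity) triples -- the image index
#' uniform over the supplied set, the offset uniform on [0, 360), the
#' velocity from a zero-mean normal with standard deviation `velocity_sd`
#' -- simulates each clip, and pairs it with its exact mirror partner
#' (receptor order reversed, velocity negated), enforcing left-right
#' symmetry of the ensemble.
#'
#' @param images Tibble with an `image` list-column (e.g. from
#'   [synth_image_set()]) or a plain list of `emd_image` objects.
#' @param n_motions Number of independent motion draws (the ensemble has
#'   `2 * n_motions` clips).
#' @param seed Integer seed; the ensemble is fully reproducible.
#' @param cfg A [photoreceptor_config()].
#' @param velocity_sd Standard deviation of the velocity prior, deg/s.
#' @return A tibble of class `emd_ensemble` with columns `clip_id`,
#'   `pair_id`, `member` (`"draw"`/`"mirror"`), `image_id`, `velocity`,
#'   `offset`, and `clip` (list-column of `motion_clip`). The configuration
#'   and seed are stored as attributes.
#' @export
build_ensemble <- function(images, n_motions, seed = 1L,
                           cfg = photoreceptor_config(), velocity_sd = 90) {
  img_list <- if (is.data.frame(images)) images$image else images
  if (length(img_list) == 0L) stop("`images` is empty.", call. = FALSE)
  stopifnot(n_motions >= 1)
  draws <- withr::with_seed(as.integer(seed), {
    list(idx = sample.int(length(img_list), n_motions, replace = TRUE),
         offset = stats::runif(n_motions, 0, 360),
         velocity = stats::rnorm(n_motions, 0, velocity_sd))
  })
  blurred <- lapply(img_list, blur_panorama, cfg = cfg)
  clips <- vector("list", 2L * n_motions)
  for (j in seq_len(n_motions)) {
    cl <- photoreceptor_response(img_list[[draws$idx[j]]], draws$velocity[j],
                                 draws$offset[j], cfg,
                                 blurred = blurred[[draws$idx[j]]])
    clips[[2L * j - 1L]] <- cl
    clips[[2L * j]] <- mirror_clip(cl)
  }
  out <- tibble::tibble(
    clip_id = seq_len(2L * n_motions),
    pair_id = rep(seq_len(n_motions), each = 2L),
    member = rep(c("draw", "mirror"), n_motions),
    image_id = rep(draws$idx, each = 2L),
    velocity = as.vector(rbind(draws$velocity, -draws$velocity)),
    offset = rep(draws$offset, each = 2L),
    clip = clips
  )
  attr(out, "cfg") <- cfg
  attr(out, "seed") <- as.integer(seed)
  attr(out, "velocity_sd") <- velocity_sd
  attr(out, "mirror_paired") <- TRUE
  class(out) <- c("emd_ensemble", class(out))
  out
}

#' Filtered-channel readouts for every clip of an ensemble
#'
#' Applies the correlator's `f`/`g` filter pair to every clip and reads
#' out the final time point of each channel -- the instantaneous value all
#' models use as their velocity estimate. Channels of mirror partners are
#' exact receptor-order swaps of each other.
#'
#' @param ensemble An [`emd_ensemble`][build_ensemble].
#' @param kernels Kernels from [make_kernels()].
#' @return A tibble with `clip_id`, `pair_id`, `member`, `velocity`, and
#'   one column per channel (`f1`, `g1`, ..., ordered by receptor).
#' @export
ensemble_channels <- function(ensemble, kernels = make_kernels()) {
  nt <- ncol(ensemble$clip[[1L]]$V)
  nr <- nrow(ensemble$clip[[1L]]$V)
  n <- nrow(ensemble)
  # stack all receptor traces as columns and filter once per kernel
  big <- matrix(unlist(lapply(ensemble$clip, function(cl) t(cl$V)),
                       use.names = FALSE), nrow = nt)
  fr <- causal_conv(big, kernels$f)[nt, ]
  gr <- causal_conv(big, kernels$g)[nt, ]
  Fm <- matrix(fr, nrow = nr)              # receptor x clip
  Gm <- matrix(gr, nrow = nr)
  out <- tibble::tibble(clip_id = ensemble$clip_id, pair_id = ensemble$pair_id,
                        member = ensemble$member, velocity = ensemble$velocity)
  for (i in seq_len(nr)) {
    out[[paste0("f", i)]] <- Fm[i, ]
    out[[paste0("g", i)]] <- Gm[i, ]
  }
  attr(out, "n_receptors") <- nr
  out
}
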