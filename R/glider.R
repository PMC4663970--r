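# Glider stimuli: binary space-time movies with an enforced 2- or 3-point
# correlation of chosen parity and direction, and the benchmark protocol
# that turns a fitted model into a predicted response table.

#' Generate a glider stimulus
#'
#' Builds a binary (+/-1) space-time movie in which a designated pixel
#' product is constrained to `parity`. The first frame (and first column,
#' where the recursion needs it) is independent fair +/-1; every later
#' pixel is set deterministically. For rightward stimuli the recursions
#' are: 2-point `s(x,t) = parity * s(x-1,t-1)`; 3-point converging
#' `s(x,t) = parity * s(x-1,t-1) * s(x,t-1)` (two early points, one late);
#' 3-point diverging `s(x,t) = parity * s(x-1,t-1) * s(x-1,t)` (one early
#' point, two late -- the space-mirrored time reversal of the converging
#' rule). Leftward stimuli are the spatial reflection of rightward ones.
#'
#' @param type `"2pt"`, `"3pt_conv"` or `"3pt_div"`.
#' @param parity +1 or -1 (the enforced product).
#' @param direction `"right"` or `"left"`.
#' @param seed Integer seed for the random seed pixels.
#' @param width Width in pixels (>= 3); default 72 pixels of 5 degrees,
#'   spanning 360 degrees.
#' @param n_frames Number of frames; default 120 (3 s at 40 Hz).
#' @param pixel_size Pixel size in degrees.
#' @param frame_rate Update rate in Hz.
#' @return An object of class `glider_stimulus`: list with `frames`
#'   (space-by-time +/-1 matrix) and the stimulus parameters.
#' @export
make_glider <- function(type = c("2pt", "3pt_conv", "3pt_div"),
                        parity = 1, direction = c("right", "left"),
                        seed = 1L, width = 72L, n_frames = 120L,
                        pixel_size = 5, frame_rate = 40) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  stopifnot(parity %in% c(-1, 1), width >= 3L, n_frames >= 2L)
  s <- withr::with_seed(as.integer(seed), {
    m <- matrix(NA_real_, width, n_frames)
    m[, 1L] <- sample(c(-1, 1), width, replace = TRUE)
    m[1L, ] <- sample(c(-1, 1), n_frames, replace = TRUE)
    m
  })
  for (t in 2:n_frames) {
    for (x in 2:width) {
      s[x, t] <- switch(type,
        "2pt" = parity * s[x - 1L, t - 1L],
        "3pt_conv" = parity * s[x - 1L, t - 1L] * s[x, t - 1L],
        "3pt_div" = parity * s[x - 1L, t - 1L] * s[x - 1L, t]
      )
    }
  }
  if (direction == "left") s <- s[rev(seq_len(width)), , drop = FALSE]
  structure(list(frames = s, glider_type = type, parity = parity,
                 direction = direction, seed = as.integer(seed),
                 pixel_size = pixel_size, frame_rate = frame_rate),
            class = "glider_stimulus")
}

#' Audit the enforced correlations of a glider stimulus
#'
#' Exhaustively checks every enforced pair/triple product against the
#' stimulus parity, making the generation convention machine-checkable.
#'
#' @param stim A [make_glider()] stimulus.
#' @return `TRUE` invisibly if all products equal the parity; otherwise
#'   an error.
#' @export
audit_glider <- function(stim) {
  s <- stim$frames
  if (stim$direction == "left") s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
  w <- nrow(s); nf <- ncol(s)
  xs <- 2:w; ts <- 2:nf
  prod <- switch(stim$glider_type,
    "2pt" = s[xs, ts] * s[xs - 1L, ts - 1L],
    "3pt_conv" = s[xs, ts] * s[xs - 1L, ts - 1L] * s[xs, ts - 1L],
    "3pt_div" = s[xs, ts] * s[xs - 1L, ts - 1L] * s[xs - 1L, ts]
  )
  if (!all(prod == stim$parity)) {
    stop("Glider audit failed: an enforced product differs from the parity.",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Glider benchmark protocol parameters
#'
#' @param n_reps Random instantiations per condition (default 25).
#' @param n_detectors Local motion estimators averaged (default 60,
#'   spaced by the receptor spacing).
#' @param duration Stimulus duration, seconds.
#' @param frame_rate Update rate, Hz.
#' @param pixel_size Pixel size, degrees.
#' @param width Stimulus width in pixels (default 72, spanning 360
#'   degrees with periodic wrap).
#' @param readout_window Averaging window at the end of the stimulus,
#'   seconds (default: the last 2 s).
#' @param conditions Tibble of (type, parity) conditions; default the six
#'   canonical ones.
#' @return A list of class `glider_protocol`.
#' @export
glider_protocol <- function(n_reps = 25L, n_detectors = 60L, duration = 3,
                            frame_rate = 40, pixel_size = 5, width = 72L,
                            readout_window = 2,
                            conditions = NULL) {
  conditions <- conditions %||% tibble::tibble(
    type = c("2pt", "2pt", "3pt_conv", "3pt_conv", "3pt_div", "3pt_div"),
    parity = c(1, -1, 1, -1, 1, -1)
  )
  structure(list(n_reps = n_reps, n_detectors = n_detectors,
                 duration = duration, frame_rate = frame_rate,
                 pixel_size = pixel_size, width = width,
                 readout_window = readout_window, conditions = conditions),
            class = "glider_protocol")
}

# Model output time course for one stimulus: photoreceptor filtering at
# n_detectors + n_extra positions, temporal f/g filtering, model signal
# per detector (each detector reads a triple of adjacent positions).
glider_model_trace <- function(model, stim, protocol, cfg, kernels) {
  n_pos <- protocol$n_detectors + cfg$n_receptors - 1L
  positions <- (seq_len(n_pos) - 1L) * cfg$spacing
  V <- movie_response(stim$frames, stim$pixel_size, 1 / stim$frame_rate,
                      positions, cfg)
  if (!is.null(model$front_end)) {
    V <- matrix(predict_front_end(model$front_end, V), nrow(V), ncol(V))
  }
  Fc <- t(causal_conv(t(V), kernels$f))  # position x time
  Gc <- t(causal_conv(t(V), kernels$g))
  d <- seq_len(protocol$n_detectors)
  ch <- list(f1 = Fc[d, , drop = FALSE], g1 = Gc[d, , drop = FALSE],
             f2 = Fc[d + 1L, , drop = FALSE], g2 = Gc[d + 1L, , drop = FALSE])
  if (cfg$n_receptors >= 3L) {
    ch$f3 <- Fc[d + 2L, , drop = FALSE]
    ch$g3 <- Gc[d + 2L, , drop = FALSE]
  }
  model_signal(model, ch) # detector x time
}

#' Predicted glider responses of a model
#'
#' Runs the benchmark protocol: for each condition and each of `n_reps`
#' seeds, generates the rightward and leftward stimulus, filters it
#' through the photoreceptor front end and the correlator kernels at
#' `n_detectors` positions, evaluates the model, and averages the output
#' over the detectors and over the final `readout_window` seconds.
#' Leftward responses are negated and pooled with rightward ones. The
#' table is normalized so the mean response to the positive 2-point
#' glider is exactly 1 (if that mean is zero, raw values are returned
#' with a warning).
#'
#' @param model An [emd_model()] (typically `fit$model` from
#'   [fit_estimator()]).
#' @param protocol A [glider_protocol()].
#' @param cfg A [photoreceptor_config()]; its `dt` must divide the frame
#'   interval.
#' @param kernels [make_kernels()] on the same `dt`.
#' @param seed Base seed; rep `k` uses `seed + k - 1`.
#' @return A tibble of class `glider_response_table` with columns `type`,
#'   `parity`, `response` (normalized mean), `sem`, `raw_mean`,
#'   `raw_sem`, `n_reps`.
#' @export
glider_response <- function(model, protocol = glider_protocol(),
                            cfg = photoreceptor_config(),
                            kernels = make_kernels(dt = cfg$dt),
                            seed = 100L) {
  nt <- as.integer(round(protocol$duration / cfg$dt))
  keep <- nt - as.integer(round(protocol$readout_window / cfg$dt)) + seq_len(
    as.integer(round(protocol$readout_window / cfg$dt)))
  n_frames <- as.integer(round(protocol$duration * protocol$frame_rate))
  per_cond <- function(type, parity) {
    vals <- vapply(seq_len(protocol$n_reps), function(k) {
      resp_dir <- vapply(c("right", "left"), function(dir) {
        stim <- make_glider(type, parity, dir, seed = seed + k - 1L,
                            width = protocol$width, n_frames = n_frames,
                            pixel_size = protocol$pixel_size,
                            frame_rate = protocol$frame_rate)
        tr <- glider_model_trace(model, stim, protocol, cfg, kernels)
        mean(tr[, keep])
      }, numeric(1))
      (resp_dir[["right"]] - resp_dir[["left"]]) / 2
    }, numeric(1))
    c(mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)))
  }
  res <- mapply(per_cond, protocol$conditions$type, protocol$conditions$parity)
  out <- tibble::tibble(
    type = protocol$conditions$type,
    parity = protocol$conditions$parity,
    raw_mean = unname(res["mean", ]),
    raw_sem = unname(res["sem", ]),
    n_reps = protocol$n_reps
  )
  norm_row <- which(out$type == "2pt" & out$parity == 1)
  norm <- if (length(norm_row) == 1L) out$raw_mean[norm_row] else NA_real_
  if (is.na(norm) || norm == 0) {
    warning("Zero or missing positive 2-point response; returning raw values.",
            call. = FALSE)
    out$response <- out$raw_mean
    out$sem <- out$raw_sem
  } else {
    out$response <- out$raw_mean / norm
    out$sem <- out$raw_sem / abs(norm)
  }
  class(out) <- c("glider_response_table", class(out))
  out
}
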