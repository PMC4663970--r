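#' Convert an intensity image to contrast
#'
#' Rescales a nonnegative intensity image to the contrast scale
#' \eqn{c = (I - I_0)/I_0}, where \eqn{I_0} is the mean intensity over the
#' whole image. The result has zero mean by construction and is bounded
#' below by -1 whenever the intensities are nonnegative.
#'
#' @param intensity A numeric matrix (or vector) of nonnegative intensities.
#' @return A contrast array of the same shape, with zero mean.
#' @examples
#' intensity_to_contrast(matrix(c(1, 3), 2, 2)) # +/- 0.5
#' @export
intensity_to_contrast <- function(intensity) {
  if (!is.numeric(intensity)) stop("`intensity` must be numeric.", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("`intensity` must be finite and nonnegative.", call. = FALSE)
  }
  i0 <- mean(intensity)
  if (i0 <= 0) {
    stop("Image has zero mean intensity; contrast is undefined.", call. = FALSE)
  }
  (intensity - i0) / i0
}

# Internal constructor for the panoramic 1-D image type.
new_emd_image <- function(contrast, source_tag, seed = NULL, pixel_pitch = 1) {
  stopifnot(is.numeric(contrast), length(contrast) * pixel_pitch == 360)
  structure(list(contrast = as.numeric(contrast), pixel_pitch = pixel_pitch,
                 source_tag = source_tag, seed = seed),
            class = "emd_image")
}

#' @export
print.emd_image <- function(x, ...) {
  cat(sprintf("<emd_image> %d px x %g deg (%s), sd = %.3f\n",
              length(x$contrast), x$pixel_pitch, x$source_tag,
              stats::sd(x$contrast)))
  invisible(x)
}

#' Reduce a 2-D contrast image to a 360-degree panoramic row
#'
#' Emulates the vertical extent of the photoreceptor's acceptance field by
#' blurring each column with a Gaussian (FWHM 5.7 degrees, truncated at
#' +/- 3 sigma and renormalized; reflective padding at the top and bottom
#' edges), extracts the central row, tiles it reflectively about its own
#' ends until 360 degrees are covered (crop centered on the original row),
#' and block-averages the result down to 1-degree pixels.
#'
#' @param contrast_image Numeric matrix of contrasts, rows x columns.
#' @param pixel_pitch Angular size of one input pixel in degrees. One
#'   output degree must be an integer number of input pixels.
#' @param blur_fwhm Full width at half maximum of the vertical blur, degrees.
#' @param out_pitch Output pixel pitch in degrees (fixed grid of 360/out_pitch
#'   pixels; only 1 is supported downstream).
#' @return An [`emd_image`][synth_image] of length 360.
#' @export
make_row_image <- function(contrast_image, pixel_pitch = 1, blur_fwhm = 5.7,
                           out_pitch = 1) {
  stopifnot(is.matrix(contrast_image), pixel_pitch > 0)
  m <- out_pitch / pixel_pitch
  if (abs(m - round(m)) > 1e-9) {
    stop("One output pixel must span an integer number of input pixels.",
         call. = FALSE)
  }
  m <- as.integer(round(m))
  if (ncol(contrast_image) < m) {
    stop("Image is narrower than one output pixel.", call. = FALSE)
  }
  k <- gauss_kernel(blur_fwhm, pixel_pitch)
  half <- (length(k) - 1L) %/% 2L
  nr <- nrow(contrast_image)
  # reflective padding of rows, then column-wise blur
  idx <- c(rev(seq_len(min(half, nr))), seq_len(nr),
           rev(seq_len(nr))[seq_len(min(half, nr))])
  if (half > nr) { # very short images: recycle reflections
    ref <- c(seq_len(nr), rev(seq_len(nr)))
    idx <- ref[((-half):(nr + half - 1L)) %% (2L * nr) + 1L]
  }
  padded <- contrast_image[idx, , drop = FALSE]
  blurred <- apply(padded, 2L, function(col)
    stats::filter(col, k, method = "convolution", sides = 2L))
  central <- as.numeric(blurred[half + (nr %/% 2L + 1L), ])
  row360 <- reflect_tile(central, n_out = as.integer(360 / out_pitch) * m)
  out <- colMeans(matrix(row360, nrow = m))
  new_emd_image(out, source_tag = "natural", pixel_pitch = out_pitch)
}

# Reflectively tile a row about its own ends until n_out pixels are
# covered, cropping centered on the original row.
reflect_tile <- function(row, n_out) {
  L <- length(row)
  n_rep <- ceiling(n_out / L) + 2L
  # middle piece (index n_rep + 1) is the original row; neighbours alternate
  pieces <- lapply(seq_len(2L * n_rep + 1L), function(j) {
    if ((j - n_rep - 1L) %% 2L == 0L) row else rev(row)
  })
  ext <- unlist(pieces, use.names = FALSE)
  center <- n_rep * L + (L + 1L) / 2       # center of the middle (original) copy
  start <- as.integer(round(center - n_out / 2 + 0.5))
  ext[start:(start + n_out - 1L)]
}

#' Parameters of the synthetic panoramic image generator
#'
#' The generator draws a stationary Gaussian random field on the 360-degree
#' circle with amplitude spectrum proportional to \eqn{k^{-slope}} (so
#' spatial correlations decay with distance) and passes it through a
#' monotone sinh-arcsinh pointwise map whose tailweight is solved by moment
#' matching so the marginal kurtosis equals `target_kurtosis`, with skew
#' controlled by `asymmetry` (positive values give a heavy bright tail, the
#' light-dark asymmetry of natural scenes). Defaults emulate contrast
#' statistics after photoreceptor filtering of natural scenes: strongly
#' heavy-tailed (kurtosis 8) and positively skewed.
#'
#' @param spectral_slope Exponent of the amplitude-spectrum power law.
#' @param asymmetry Skew parameter of the pointwise map; 0 gives a
#'   symmetric marginal, > 0 positive skew.
#' @param target_kurtosis Marginal kurtosis (standardized fourth central
#'   moment, no excess shift) of the generated contrasts. Must be >= 1;
#'   values below the sinh-arcsinh family's floor (about 2.6 for symmetric
#'   maps) are rejected as unattainable.
#' @param contrast_sd Marginal standard deviation of the contrast.
#' @param seed Integer seed; fixed seed gives identical images.
#' @return A list of class `synth_image_params`.
#' @export
synth_image_params <- function(spectral_slope = 1, asymmetry = 0.3,
                               target_kurtosis = 8, contrast_sd = 0.35,
                               seed = 1L) {
  if (target_kurtosis < 1) {
    stop("target_kurtosis < 1 is unattainable (symmetric Bernoulli floor).",
         call. = FALSE)
  }
  structure(list(spectral_slope = spectral_slope, asymmetry = asymmetry,
                 target_kurtosis = target_kurtosis, contrast_sd = contrast_sd,
                 seed = as.integer(seed)),
            class = "synth_image_params")
}

# sinh-arcsinh transform of a standard normal variate.
shash_map <- function(z, delta, eps) sinh((asinh(z) + eps) / delta)

# Standardized moments of shash_map(Z) for Z ~ N(0,1), by fine quantile
# quadrature (deterministic, no sampling).
shash_kurtosis <- function(delta, eps, n_quad = 20000L) {
  z <- stats::qnorm((seq_len(n_quad) - 0.5) / n_quad)
  x <- shash_map(z, delta, eps)
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

# Solve the tailweight delta so the marginal kurtosis hits the target.
solve_shash_delta <- function(target_kurtosis, eps) {
  if (abs(eps) < 1e-12 && abs(target_kurtosis - 3) < 1e-9) return(1)
  lo <- 0.05
  hi <- 25
  f <- function(d) shash_kurtosis(d, eps) - target_kurtosis
  if (f(lo) < 0 || f(hi) > 0) {
    stop(sprintf(paste0("target_kurtosis = %g is not attainable by the ",
                        "sinh-arcsinh family at asymmetry = %g ",
                        "(attainable range is about [%0.2f, %0.0f])."),
                 target_kurtosis, eps, shash_kurtosis(hi, eps),
                 shash_kurtosis(lo, eps)),
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-7)$root
}

# Fourier basis (360 x 2K) and theoretical marginal SD for the 1/f^slope
# circle field; cached per slope within a call via force().
spectral_basis <- function(n = 360L, slope = 1) {
  kk <- seq_len(n %/% 2L)
  amp <- kk^(-slope)
  x <- seq_len(n) - 1L
  B <- matrix(0, n, 2L * length(kk))
  for (j in seq_along(kk)) {
    ph <- 2 * pi * kk[j] * x / n
    B[, 2L * j - 1L] <- amp[j] * cos(ph)
    B[, 2L * j] <- amp[j] * sin(ph)
  }
  list(B = B, sd = sqrt(sum(amp^2)))
}

#' Generate synthetic panoramic contrast images
#'
#' @param params A [synth_image_params()] object.
#' @param n Number of images to generate.
#' @return For `synth_image()`, a single [`emd_image`][make_row_image]; for
#'   `synth_image_set()`, a tibble with columns `image_id` and `image`
#'   (list-column of `emd_image`).
#' @examples
#' img <- synth_image(synth_image_params(seed = 7))
#' length(img$contrast) # 360
#' @export
synth_image_set <- function(params = synth_image_params(), n = 1L) {
  stopifnot(inherits(params, "synth_image_params"), n >= 1)
  delta <- solve_shash_delta(params$target_kurtosis, params$asymmetry)
  basis <- spectral_basis(360L, params$spectral_slope)
  nk <- ncol(basis$B)
  # standardize the mapped marginal by the same deterministic quadrature
  zq <- stats::qnorm((seq_len(20000L) - 0.5) / 20000L)
  xq <- shash_map(zq, delta, params$asymmetry)
  mu <- mean(xq)
  sc <- params$contrast_sd / stats::sd(xq)
  imgs <- withr::with_seed(params$seed, {
    coef <- matrix(stats::rnorm(nk * n), nk, n)
    Z <- basis$B %*% coef / basis$sd      # exact N(0,1) marginals
    X <- (shash_map(Z, delta, params$asymmetry) - mu) * sc
    lapply(seq_len(n), function(j) {
      new_emd_image(X[, j], source_tag = "synthetic", seed = params$seed)
    })
  })
  tibble::tibble(image_id = seq_len(n), image = imgs)
}

#' @rdname synth_image_set
#' @export
synth_image <- function(params = synth_image_params()) {
  synth_image_set(params, n = 1L)$image[[1L]]
}

#' Read a plain (ASCII, P2) PGM grayscale image
#'
#' Minimal reader for the plain-text PGM variant, the text route for
#' supplying natural images to [intensity_to_contrast()] and
#' [make_row_image()].
#'
#' @param path Path to a P2 PGM file.
#' @return A numeric intensity matrix.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (tok[1L] != "P2") stop("Only plain (P2) PGM files are supported.",
                            call. = FALSE)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("Corrupt PGM: wrong pixel count.",
                                  call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
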