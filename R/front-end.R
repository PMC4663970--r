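# Front-end (photoreceptor-output) nonlinearities: static monotone
# transforms y = h(V) inserted after the photoreceptor's spatiotemporal
# filtering but before the correlator's temporal filters.

#' Specify a front-end nonlinearity
#'
#' Three rank-based transforms of the pooled photoreceptor signal
#' distribution: `"gaussianize"` maps ranks (scaled to (0, 1)) through the
#' inverse Gaussian CDF, producing outputs with kurtosis 3;
#' `"equalize"` maps ranks to a uniform distribution on \[-1, 1\]
#' (kurtosis 1.8); `"binarize"` maps percentile bins alternately to -1 and
#' +1 starting with -1 for the lowest bin -- the default single threshold
#' at the median yields the symmetric Bernoulli output (kurtosis 1, the
#' minimum of any distribution), and `thresholds = c(0.25, 0.75)` gives
#' the two-step variant (outer quartiles to -1, inner half to +1). Ties
#' share the mean rank.
#'
#' @param kind One of `"gaussianize"`, `"equalize"`, `"binarize"`.
#' @param thresholds Percentile thresholds for `"binarize"`, strictly
#'   increasing, in (0, 1).
#' @return A list of class `front_end_spec`.
#' @export
front_end <- function(kind = c("gaussianize", "equalize", "binarize"),
                      thresholds = 0.5) {
  kind <- match.arg(kind)
  if (kind == "binarize") {
    stopifnot(all(thresholds > 0), all(thresholds < 1),
              !is.unsorted(thresholds, strictly = TRUE))
  }
  structure(list(kind = kind, thresholds = thresholds),
            class = "front_end_spec")
}

# Rank-based transform of a pooled sample. Ties share the mean rank.
front_end_transform <- function(values, fe) {
  n <- length(values)
  if (n == 0L) stop("Empty pool: nothing to transform.", call. = FALSE)
  switch(fe$kind,
    equalize = {
      r <- rank(values, ties.method = "average")
      if (n == 1L) return(0)
      2 * (r - 1) / (n - 1) - 1
    },
    gaussianize = {
      r <- rank(values, ties.method = "average")
      stats::qnorm(r / (n + 1))
    },
    binarize = {
      qs <- stats::quantile(values, fe$thresholds, names = FALSE, type = 7L)
      bin <- findInterval(values, qs)
      ifelse(bin %% 2L == 0L, -1, 1)
    }
  )
}

#' Fit a front-end lookup map on a pool of photoreceptor values
#'
#' Builds the monotone lookup `h` by transforming the pooled values and
#' recording the (sorted value, transformed value) pairs; new data are
#' mapped through this lookup by linear interpolation (constant beyond
#' the pool's range). By default the map is both fitted on and applied to
#' the full pooled ensemble, as the estimation protocol prescribes.
#'
#' @param values Numeric pool (all receptors, time points and motions).
#' @param fe A [front_end()] specification.
#' @return An object of class `front_end_fit`.
#' @export
fit_front_end <- function(values, fe) {
  if (length(values) == 0L) stop("Empty pool.", call. = FALSE)
  y <- front_end_transform(values, fe)
  o <- order(values)
  xs <- values[o]
  ys <- y[o]
  keep <- !duplicated(xs)
  # thin the lookup to keep interpolation cheap on huge pools
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) > 20000L) {
    pick <- unique(round(seq(1L, length(xs), length.out = 20000L)))
    xs <- xs[pick]; ys <- ys[pick]
  }
  structure(list(spec = fe, x = xs, y = ys), class = "front_end_fit")
}

#' @rdname fit_front_end
#' @param object A `front_end_fit`.
#' @param newdata Numeric values to transform.
#' @export
predict_front_end <- function(object, newdata) {
  stopifnot(inherits(object, "front_end_fit"))
  if (object$spec$kind == "binarize") {
    # step map: interpolation would smooth the steps
    out <- object$y[pmax(1L, findInterval(newdata, object$x))]
    out[newdata < object$x[1L]] <- object$y[1L]
    return(out)
  }
  stats::approx(object$x, object$y, xout = newdata, rule = 2L)$y
}

#' Apply a front-end nonlinearity to an ensemble
#'
#' Pools all photoreceptor values of the ensemble (all receptors, time
#' points and motions sorted together), applies the rank-based transform,
#' and returns the ensemble with transformed clips plus the fitted lookup
#' map (attached as attribute `"front_end_fit"`, for later application to
#' new stimuli such as gliders). With `pooled = FALSE` the lookup is
#' fitted on the clips whose `pair_id` is in `train_pairs` only and
#' applied everywhere by interpolation (the leakage-free mode).
#'
#' @param ensemble An [`emd_ensemble`][build_ensemble].
#' @param fe A [front_end()] specification.
#' @param pooled Fit the lookup on the full ensemble (default) or on
#'   `train_pairs` only.
#' @param train_pairs Pair ids used to fit the lookup when
#'   `pooled = FALSE`.
#' @return The transformed ensemble.
#' @export
apply_front_end <- function(ensemble, fe, pooled = TRUE, train_pairs = NULL) {
  stopifnot(inherits(ensemble, "emd_ensemble"))
  vals <- unlist(lapply(ensemble$clip, function(cl) cl$V), use.names = FALSE)
  if (pooled) {
    y <- front_end_transform(vals, fe)
    fit <- fit_front_end(vals, fe)
    pos <- 0L
    clips <- lapply(ensemble$clip, function(cl) {
      nv <- length(cl$V)
      Vt <- matrix(y[pos + seq_len(nv)], nrow(cl$V), ncol(cl$V))
      pos <<- pos + nv
      rownames(Vt) <- rownames(cl$V)
      cl$V <- Vt
      cl
    })
  } else {
    if (is.null(train_pairs)) stop("`train_pairs` required when pooled = FALSE.",
                                   call. = FALSE)
    in_train <- ensemble$pair_id %in% train_pairs
    pool <- unlist(lapply(ensemble$clip[in_train], function(cl) cl$V),
                   use.names = FALSE)
    fit <- fit_front_end(pool, fe)
    clips <- lapply(ensemble$clip, function(cl) {
      Vt <- matrix(predict_front_end(fit, cl$V), nrow(cl$V), ncol(cl$V))
      rownames(Vt) <- rownames(cl$V)
      cl$V <- Vt
      cl
    })
  }
  out <- ensemble
  out$clip <- clips
  attr(out, "front_end_fit") <- fit
  out
}
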