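# Motion-estimator architectures. Every operation acts elementwise on a
# set of named filtered channels (f1, g1, f2, g2, f3, g3), so the same
# code path serves scalar readouts, full time series, and detector arrays.

# Normalize the various channel containers to a named list of arrays plus
# an optional readout index (set when the input is a filter bank).
as_channels <- function(x) {
  if (inherits(x, "emd_bank")) {
    ch <- lapply(seq_len(nrow(x$channels)), function(i) x$channels[i, ])
    names(ch) <- rownames(x$channels)
    return(list(ch = ch, readout = x$readout_index))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(list(ch = as.list(x), readout = NULL))
  }
  if (is.list(x)) return(list(ch = x, readout = NULL))
  stop("Cannot interpret channels: supply an emd_bank, a named numeric ",
       "vector, or a named list of arrays.", call. = FALSE)
}

channel_finish <- function(parsed, value) {
  if (!is.null(parsed$readout)) value[parsed$readout] else value
}

check_pair <- function(pair, n_avail, allow_nonadjacent = FALSE) {
  stopifnot(length(pair) == 2L, all(pair >= 1), all(pair <= n_avail))
  if (abs(pair[2L] - pair[1L]) != 1L && !allow_nonadjacent) {
    stop("Non-adjacent receptor pair; set `allow_nonadjacent = TRUE` for ",
         "next-nearest-neighbour correlators.", call. = FALSE)
  }
}

#' Hassenstein-Reichardt correlator signal
#'
#' Computes \eqn{R = (f*V_i)(g*V_j) - (g*V_i)(f*V_j)} for a receptor pair
#' `(i, j)`. The output negates under receptor swap (mirror antisymmetry).
#'
#' @param x Channels: an [`emd_bank`][filter_bank] (returns the value at
#'   the readout time point), a named numeric vector, or a named list of
#'   arrays (`f1`, `g1`, ...; returns the same shape).
#' @param pair Receptor indices `(i, j)`; must be adjacent unless
#'   `allow_nonadjacent = TRUE` (next-nearest-neighbour correlators are
#'   legitimate components of the three-input model).
#' @param allow_nonadjacent Permit `|i - j| > 1`.
#' @return The correlator output (scalar for a bank input).
#' @export
hrc <- function(x, pair = c(1L, 2L), allow_nonadjacent = FALSE) {
  p <- as_channels(x)
  n_avail <- length(p$ch) %/% 2L
  check_pair(pair, n_avail, allow_nonadjacent)
  i <- pair[1L]; j <- pair[2L]
  val <- p$ch[[paste0("f", i)]] * p$ch[[paste0("g", j)]] -
    p$ch[[paste0("g", i)]] * p$ch[[paste0("f", j)]]
  channel_finish(p, val)
}

#' Converging 3-point correlator signal
#'
#' A third-order, mirror-antisymmetric correlator that pairs low-pass
#' filtered signals with one high-pass filtered signal from the adjacent
#' receptor, sensitive to the triple correlations that 3-point glider
#' stimuli enforce. Two channel assignments are provided, since the
#' usual diagrammatic definition admits both readings:
#' `"two_site"`: \eqn{(f*V_i)(f*V_j)(g*V_j) - (f*V_j)(f*V_i)(g*V_i)};
#' `"squared"`: \eqn{(f*V_i)^2(g*V_j) - (f*V_j)^2(g*V_i)}.
#'
#' @inheritParams hrc
#' @param variant `"two_site"` or `"squared"`.
#' @export
converging_3pt <- function(x, variant = c("two_site", "squared"),
                           pair = c(1L, 2L)) {
  variant <- match.arg(variant)
  p <- as_channels(x)
  check_pair(pair, length(p$ch) %/% 2L)
  fi <- p$ch[[paste0("f", pair[1L])]]; fj <- p$ch[[paste0("f", pair[2L])]]
  gi <- p$ch[[paste0("g", pair[1L])]]; gj <- p$ch[[paste0("g", pair[2L])]]
  val <- switch(variant,
    two_site = fi * fj * gj - fj * fi * gi,
    squared = fi^2 * gj - fj^2 * gi
  )
  channel_finish(p, val)
}

#' HRC-quadrant signals
#'
#' Splits the correlator's multiplication into the four sign quadrants:
#' \eqn{Q_{ab} = [f*V_i]_a [g*V_j]_b - [g*V_i]_b [f*V_j]_a}, where
#' \eqn{[x]_+ = \max(x, 0)}, \eqn{[x]_- = \min(x, 0)}, the first index is
#' the sign of the low-pass channel and the second the sign of the
#' high-pass channel. The four quadrants sum exactly to the HRC, and each
#' is mirror-antisymmetric.
#'
#' @inheritParams hrc
#' @return A list with elements `pp`, `pm`, `mp`, `mm` (same shape as the
#'   channels; for a bank input, scalars at the readout point).
#' @export
quadrant_signals <- function(x, pair = c(1L, 2L)) {
  p <- as_channels(x)
  check_pair(pair, length(p$ch) %/% 2L)
  pos <- function(z) pmax(z, 0)
  neg <- function(z) pmin(z, 0)
  fi <- p$ch[[paste0("f", pair[1L])]]; fj <- p$ch[[paste0("f", pair[2L])]]
  gi <- p$ch[[paste0("g", pair[1L])]]; gj <- p$ch[[paste0("g", pair[2L])]]
  q <- list(
    pp = pos(fi) * pos(gj) - pos(gi) * pos(fj),
    pm = pos(fi) * neg(gj) - neg(gi) * pos(fj),
    mp = neg(fi) * pos(gj) - pos(gi) * neg(fj),
    mm = neg(fi) * neg(gj) - neg(gi) * neg(fj)
  )
  lapply(q, function(v) channel_finish(p, v))
}

#' Weighted 4-quadrant model signal
#'
#' Linear combination \eqn{Q = \sum_{ab} w_{ab} Q_{ab}} of the four
#' HRC-quadrants. Equal weights reproduce the HRC exactly.
#'
#' @inheritParams hrc
#' @param w Numeric weights, length 4, in the order `(pp, pm, mp, mm)`.
#' @export
weighted_quadrant <- function(x, w = c(1, 1, 1, 1), pair = c(1L, 2L)) {
  stopifnot(length(w) == 4L, all(is.finite(w)))
  q <- quadrant_signals(x, pair)
  w[1L] * q$pp + w[2L] * q$pm + w[3L] * q$mp + w[4L] * q$mm
}

# The 4 x 4 sign-pattern matrix (rows: classes, columns: quadrants in the
# order pp, pm, mp, mm), scaled by 1/4. Row "even2" is the uniform sum, so
# even2 = HRC / 4; the two odd rows negate and the even_gt2 row is
# invariant under global contrast inversion (which swaps pp<->mm, pm<->mp).
class_pattern_matrix <- function(odd_pattern = c("lowpass", "highpass")) {
  odd_pattern <- match.arg(odd_pattern)
  lowpass_row <- c(1, 1, -1, -1) / 4   # sign of the low-pass factor
  highpass_row <- c(1, -1, 1, -1) / 4  # sign of the high-pass factor
  M <- rbind(
    even2 = c(1, 1, 1, 1) / 4,
    odd = if (odd_pattern == "lowpass") lowpass_row else highpass_row,
    oddstar = if (odd_pattern == "lowpass") highpass_row else lowpass_row,
    even_gt2 = c(1, -1, -1, 1) / 4
  )
  colnames(M) <- c("pp", "pm", "mp", "mm")
  M
}

#' Correlation-class reparameterization of the quadrant model
#'
#' Re-expresses the four HRC-quadrants in an orthogonal basis of signed
#' sums (each scaled by 1/4) that isolates correlation orders: `even2`
#' (the uniform sum -- the HRC itself, divided by 4), two classes of odd
#' higher-order correlations (`odd`, `oddstar`), and even correlations
#' above second order (`even_gt2`). The map is an invertible linear
#' bijection; [classes_to_quadrants()] is its exact inverse. Which of the
#' two odd sign patterns is labelled `odd` is configurable via
#' `odd_pattern` (`"lowpass"`: signs follow the low-pass factor).
#'
#' @param q Quadrant values: a list as returned by [quadrant_signals()] or
#'   a numeric vector of length 4 in the order `(pp, pm, mp, mm)`.
#' @param odd_pattern `"lowpass"` (default) or `"highpass"`.
#' @return A list with elements `even2`, `odd`, `oddstar`, `even_gt2`.
#' @export
correlation_classes <- function(q, odd_pattern = "lowpass") {
  if (is.numeric(q)) q <- list(pp = q[1L], pm = q[2L], mp = q[3L], mm = q[4L])
  M <- class_pattern_matrix(odd_pattern)
  out <- lapply(seq_len(4L), function(r) {
    M[r, 1L] * q$pp + M[r, 2L] * q$pm + M[r, 3L] * q$mp + M[r, 4L] * q$mm
  })
  names(out) <- rownames(M)
  out
}

#' @rdname correlation_classes
#' @param cl A list or length-4 vector of class values in the order
#'   `(even2, odd, oddstar, even_gt2)`.
#' @export
classes_to_quadrants <- function(cl, odd_pattern = "lowpass") {
  if (is.numeric(cl)) cl <- list(even2 = cl[1L], odd = cl[2L],
                                 oddstar = cl[3L], even_gt2 = cl[4L])
  Minv <- solve(class_pattern_matrix(odd_pattern))
  out <- lapply(seq_len(4L), function(r) {
    Minv[r, 1L] * cl$even2 + Minv[r, 2L] * cl$odd +
      Minv[r, 3L] * cl$oddstar + Minv[r, 4L] * cl$even_gt2
  })
  names(out) <- c("pp", "pm", "mp", "mm")
  out
}

#' Polynomial exponent table
#'
#' Enumerates all monomial exponent tuples of total degree 1 to
#' `max_order` over `arity` channels (the constant term is excluded), in
#' lexicographic order of the exponent tuple. This ordering is frozen in
#' the model file format. Counts for `max_order = 4`: 14 tuples at arity
#' 2, 69 at arity 4, 209 at arity 6.
#'
#' @param arity Number of input channels (2, 4 or 6).
#' @param max_order Maximum total degree (default 4).
#' @return Integer matrix, one row per exponent tuple.
#' @export
poly_exponents <- function(arity, max_order = 4L) {
  stopifnot(arity >= 1, max_order >= 1)
  grids <- rep(list(0:max_order), arity)
  ex <- as.matrix(rev(expand.grid(rev(grids))))
  deg <- rowSums(ex)
  ex <- ex[deg >= 1 & deg <= max_order, , drop = FALSE]
  ex <- ex[do.call(order, as.data.frame(ex)), , drop = FALSE]
  dimnames(ex) <- list(NULL, paste0("e", seq_len(arity)))
  storage.mode(ex) <- "integer"
  ex
}

# Channel sets per polynomial arity: which named channels feed the
# monomials. Pair/receptors follow the module's conventions.
poly_channel_names <- function(arity, pair = c(1L, 2L), receptors = 1:3) {
  switch(as.character(arity),
    "4" = c(paste0(c("f", "g"), pair[1L]), paste0(c("f", "g"), pair[2L])),
    "6" = as.vector(rbind(paste0("f", receptors), paste0("g", receptors))),
    stop("Unsupported arity.", call. = FALSE)
  )
}

#' Polynomial predictor features
#'
#' Builds the monomial predictor set of the polynomial nonlinearity
#' models from channel readouts. For `arity = 4` (two receptors,
#' unrestricted nonlinearity) and `arity = 6` (three receptors, extra
#' input nonlinearity) the features are all monomials of total degree 1-4
#' of the selected channels (69 and 209 features). For `arity = 2` (the
#' non-multiplicative nonlinearity \eqn{\eta(x, y)} applied
#' antisymmetrically), each feature is the mirror-antisymmetrized pair
#' \eqn{x^i y^j - x'^i y'^j} with \eqn{x = f*V_1, y = g*V_2, x' = f*V_2,
#' y' = g*V_1} (14 features).
#'
#' @param channels A data frame of channel readouts (e.g. from
#'   [ensemble_channels()]) or a named list of equal-shape arrays.
#' @param arity 2, 4 or 6.
#' @param pair Receptor pair used for arity 2 and 4.
#' @param receptors Receptors used for arity 6.
#' @param max_order Maximum total degree.
#' @return A numeric matrix, one column per feature, with the exponent
#'   table attached as attribute `"exponents"`. Column names encode the
#'   exponents (e.g. `"w1001"`).
#' @export
poly_features <- function(channels, arity, pair = c(1L, 2L),
                          receptors = 1:3, max_order = 4L) {
  ch <- if (is.data.frame(channels)) as.list(channels) else channels
  if (arity == 2L) {
    need <- c(paste0("f", c(pair, rev(pair))), paste0("g", c(pair, rev(pair))))
  } else {
    need <- poly_channel_names(arity, pair, receptors)
  }
  if (!all(need %in% names(ch))) {
    stop("Channel set does not match the requested arity/receptors: need ",
         paste(setdiff(need, names(ch)), collapse = ", "), call. = FALSE)
  }
  if (arity == 2L) {
    ex <- poly_exponents(2L, max_order)
    x1 <- ch[[paste0("f", pair[1L])]]; y1 <- ch[[paste0("g", pair[2L])]]
    x2 <- ch[[paste0("f", pair[2L])]]; y2 <- ch[[paste0("g", pair[1L])]]
    X <- vapply(seq_len(nrow(ex)), function(k) {
      x1^ex[k, 1L] * y1^ex[k, 2L] - x2^ex[k, 1L] * y2^ex[k, 2L]
    }, numeric(length(x1)))
  } else {
    ex <- poly_exponents(arity, max_order)
    vars <- lapply(poly_channel_names(arity, pair, receptors),
                   function(nm) ch[[nm]])
    X <- vapply(seq_len(nrow(ex)), function(k) {
      out <- 1
      for (v in seq_len(arity)) {
        if (ex[k, v] > 0L) out <- out * vars[[v]]^ex[k, v]
      }
      out + numeric(length(vars[[1L]]))
    }, numeric(length(vars[[1L]])))
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L) # scalar channels
  colnames(X) <- paste0("w", apply(ex, 1L, paste, collapse = ""))
  attr(X, "exponents") <- ex
  X
}

# ---- uniform model interface -------------------------------------------

#' Construct a motion-estimator model
#'
#' A uniform wrapper over all architectures, evaluable on filter banks or
#' channel arrays via [evaluate_model()]. Architectures: `"hrc"`,
#' `"conv3pt"` (with `variant`), `"quadrant"` (4 weights), `"poly2"`,
#' `"poly4"`, `"poly6"` (monomial weights in [poly_exponents()] order),
#' and `"linear"` (a weighted sum of arbitrary named component signals,
#' used for e.g. HRC + converging 3-point fits).
#'
#' @param architecture Architecture tag.
#' @param weights Numeric weights; length must match the architecture
#'   (1 for hrc/conv3pt, 4 for quadrant, 14/69/209 for the polynomials).
#' @param pair,receptors Receptor assignment.
#' @param variant Variant for `"conv3pt"`.
#' @param components For `"linear"`: list of functions `f(channels)`
#'   returning component signals.
#' @param front_end Optional fitted front-end transform (see
#'   [fit_front_end()]) applied to photoreceptor signals before temporal
#'   filtering when the model is evaluated on raw stimuli.
#' @param scale Output scale (set by the fitting routines to
#'   \eqn{r \sigma_v / \sigma_R}).
#' @return An object of class `emd_model`.
#' @export
emd_model <- function(architecture, weights = 1, pair = c(1L, 2L),
                      receptors = 1:3, variant = "two_site",
                      components = NULL, front_end = NULL, scale = 1) {
  arch <- match.arg(architecture,
                    c("hrc", "conv3pt", "quadrant", "poly2", "poly4",
                      "poly6", "linear"))
  expected <- switch(arch,
    hrc = 1L, conv3pt = 1L, quadrant = 4L,
    poly2 = nrow(poly_exponents(2L)), poly4 = nrow(poly_exponents(4L)),
    poly6 = nrow(poly_exponents(6L)),
    linear = length(components)
  )
  if (length(weights) != expected) {
    stop(sprintf("Architecture '%s' needs %d weights, got %d.",
                 arch, expected, length(weights)), call. = FALSE)
  }
  structure(list(architecture = arch, weights = as.numeric(weights),
                 pair = pair, receptors = receptors, variant = variant,
                 components = components, front_end = front_end,
                 scale = scale),
            class = "emd_model")
}

#' @export
print.emd_model <- function(x, ...) {
  cat(sprintf("<emd_model> %s (%d weight%s), scale = %.4g%s\n",
              x$architecture, length(x$weights),
              if (length(x$weights) == 1L) "" else "s", x$scale,
              if (!is.null(x$front_end)) ", with front-end" else ""))
  invisible(x)
}

# Raw (unscaled) model signal on a channel list; elementwise over arrays.
model_signal <- function(model, ch) {
  sig <- model_signal_impl(model, ch)
  tmpl <- ch[[1L]]
  if (!is.null(dim(tmpl)) && is.null(dim(sig))) dim(sig) <- dim(tmpl)
  sig
}

model_signal_impl <- function(model, ch) {
  w <- model$weights
  if (anyNA(w)) stop("Model weights are unset.", call. = FALSE)
  switch(model$architecture,
    hrc = w * hrc(ch, model$pair),
    conv3pt = w * converging_3pt(ch, model$variant, model$pair),
    quadrant = weighted_quadrant(ch, w, model$pair),
    poly2 = ,
    poly4 = ,
    poly6 = {
      arity <- as.integer(sub("poly", "", model$architecture))
      X <- poly_features(ch, arity, model$pair, model$receptors)
      drop(X %*% w)
    },
    linear = {
      sig <- 0
      for (k in seq_along(model$components)) {
        sig <- sig + w[k] * model$components[[k]](ch)
      }
      sig
    }
  )
}

#' Evaluate a motion-estimator model
#'
#' @param model An [emd_model()] with weights set.
#' @param x Channels (see [hrc()] for accepted forms).
#' @return The scaled model output; a scalar when `x` is a filter bank.
#' @export
evaluate_model <- function(model, x) {
  p <- as_channels(x)
  # poly features over time series need vector channels
  val <- if (model$architecture %in% c("poly2", "poly4", "poly6") &&
             !is.null(p$readout)) {
    sig <- model_signal(model, p$ch)
    sig[p$readout]
  } else {
    channel_finish(p, model_signal(model, p$ch))
  }
  model$scale * val
}
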