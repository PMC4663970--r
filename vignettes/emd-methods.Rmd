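---
title: "Motion estimator models, their fitting, and the glider benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion estimator models, their fitting, and the glider benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the simulation
and models it implements, the numerical choices behind them, and what
the synthetic-data pipeline can and cannot tell you about real visual
scenes.

## The estimation problem

A fly turning in place sees the whole panorama translate rigidly. The
package models this as a 360°-wide, 1°-sampled contrast row `c(x)`
moving at a constant velocity `v` drawn from a zero-mean normal prior
with SD 90 °/s — a spread representative of the animal's own rotary
behavior. Three photoreceptors spaced 5.1° apart view the row through
a Gaussian acceptance function (FWHM 5.7°) and a causal exponential
temporal kernel (10 ms):

$$V_i(t) = \int dt'\, T(t') \int dx\, M(x - x_i)\, c(x - v(t - t')).$$

Every estimator in the package is built from the same six filtered
channels $(f*V_i), (g*V_i)$, with $f(t) = t e^{-t/\tau}$, $g = df/dt$,
$\tau$ = 20 ms, and reads out its value at the final time point of an
800 ms clip simulated at 5 ms steps. An estimator's quality is the
correlation coefficient `r` between that readout and `v`; after the
output is scaled by $r \sigma_v / \sigma_R$, the mean squared error is
$\sigma_v^2 (1 - r^2)$, so `r` and MSE are interchangeable summaries.

## Discretization choices

* **Spatial integral** on the image's 1° grid: the Gaussian is
  evaluated at pixel centers, truncated at ±3σ, and renormalized to
  unit sum (mass loss below 1% before renormalization).
* **Sub-pixel translation** by linear interpolation between 1° pixels,
  with periodic wrap. The choice of interpolant is not dictated by the
  physics; the package validates the whole discretization against a
  brute-force quadrature of the double integral on a 10× finer grid
  (relative error under 2% in the tests).
* **Temporal filtering** as causal discrete convolution from zero
  initial state. The 800 ms clip length is itself the burn-in: models
  read only the final sample, long after the ~30 ms of combined filter
  memory.
* **Kernel normalization.** The temporal kernels' gain is not fixed by
  the model definition — any gain is absorbed into the fitted weights —
  so `f` is scaled to unit sum, `g` by the same factor and then
  mean-adjusted to exact zero sum so constants are annihilated despite
  truncation. This only affects numerical conditioning.
* **Mirror pairing is exact by construction.** Each sampled motion is
  paired with the clip whose receptor matrix is the row-reversed copy
  and whose velocity is negated; this is what reflecting the image,
  inverting the velocity and matching the offset would produce, without
  re-simulation. Mirror pairs are atomic in every cross-validation
  split, so both folds are exactly left–right symmetric.

## The synthetic image generator

The generator stands in for a natural-image database so the pipeline
runs with no external data. It emulates the three statistics of
photoreceptor-filtered natural contrast that matter to the estimators:

1. **heavy tails** — default marginal kurtosis 8, in the range
   characteristic of filtered natural contrast (values near 9–10 are
   typical for some databases, but it varies; 8 keeps fourth-order
   feature moments finite-sample stable at desk scale);
2. **light–dark asymmetry** — positive skew (default asymmetry 0.3),
   the property that makes unequal ON/OFF weighting profitable;
3. **spatial correlations decaying with distance** — a 1/f amplitude
   spectrum.

Construction: a stationary Gaussian field on the circle with
$k^{-1}$ amplitudes (exact N(0,1) marginals by normalization), passed
through the monotone sinh–arcsinh map
$x = \sinh((\mathrm{asinh}(z) + \varepsilon)/\delta)$. The tailweight
δ is solved by deterministic quantile quadrature so the marginal
kurtosis hits its target; ε sets the skew sign. The marginal SD is set
to 0.35, a realistic RMS contrast. Kurtosis targets below the family's
floor (≈2.6 for symmetric maps) are rejected rather than approximated.

What the generator does *not* emulate: occlusion edges, luminance
gradients within scenes, vertical structure, correlations between
skew and local variance. Consequently, passing tests establish that the
estimator hierarchy behaves as designed on inputs with natural-scene
*moments*; absolute accuracies on real image databases will differ,
and database-specific reference values (e.g. pooled kurtosis near 9.6) are
external-data checks, not targets of this package.

## The estimator hierarchy

All models are mirror-antisymmetric maps from the channel bank to a
scalar, nested by construction:

* **HRC** — $(f*V_1)(g*V_2) - (g*V_1)(f*V_2)$; a pure 2-point
  correlator.
* **Converging 3-point correlator** — two low-pass signals times one
  high-pass signal, antisymmetrized. Two channel assignments are
  implemented (`two_site` and `squared`) because the usual diagrammatic
  definition admits both readings; neither is asserted as canonical.
* **Front-end nonlinearities** — rank transforms of the pooled
  $V_i$ values (all receptors, times and motions sorted together; ties
  share the mean rank): gaussianize (output kurtosis 3), contrast
  equalize (uniform on [−1,1], kurtosis 1.8), binarize (±1, kurtosis 1,
  the minimum any distribution attains). By default the lookup is both
  fitted on and applied to the full pooled ensemble — deliberately
  leakage-tolerant, matching the estimation protocol; a train-only
  mode applies the fitted monotone lookup to held-out data by
  interpolation.
* **Weighted 4-quadrant model** — the correlator's product split by
  the sign quadrants of its two factors,
  $Q_{ab} = [f*V_1]_a [g*V_2]_b - [g*V_1]_b [f*V_2]_a$, combined with
  free weights. Equal weights are algebraically the HRC (the package
  asserts this at machine precision). An invertible Hadamard-type
  reparameterization (each pattern scaled by 1/4) isolates correlation
  classes: the uniform row is the HRC ("even = 2"); the two
  sign-alternating rows respond only to odd-order correlations; the
  fourth row to even orders above 2. Which odd row is labelled `odd`
  versus `oddstar` is configurable, since only the even-row anchoring
  is fixed by the definition.
* **Polynomial nonlinearity models** — all monomials of total degree
  1–4 of 2, 4, or 6 channels (14 antisymmetrized, 69, and 209 free
  weights; the constant is excluded as useless for a zero-mean
  velocity prior). Exponent tuples are enumerated in lexicographic
  order and that order is frozen in the JSON model format. For the 4-
  and 6-channel models, mirror antisymmetry is not imposed on the
  features; it is inherited from fitting on the exactly symmetrized
  ensemble, matching the estimation protocol.

## Fitting and selection

Weights minimize training MSE by ordinary least squares without
intercept; accuracies are reported on the held-out half of a twofold
split (mirror pairs atomic), averaged over 20 random divisions, with
the across-division SD as the error bar. All second moments are taken
about zero — the velocity prior is zero-mean and the models have no
constant term — which makes the MSE–correlation identity hold to
machine precision in-sample; the test-fold MSE is reported for the
test-scaled output so the identity holds there too. Rank-deficient
designs (possible when clips are fewer than predictors) fall back to
the minimum-norm solution with a warning rather than failing.

For predictor selection, the lasso is run on z-scored predictors
(penalty comparability across monomials of very different scales —
degree-1 versus degree-4 terms differ by orders of magnitude), on a
logarithmic penalty path spanning empty to full support; each support
is then refit by plain OLS, so the penalty never biases the reported
weights. The support-size versus accuracy curve is qualitative: the
particular sparse selection one obtains (e.g. which 16 predictors
survive) depends on the image ensemble and on grid details, so the
package makes no numerical claim about it.

## The glider benchmark

Gliders are binary ±1 movies (3 s, 40 Hz, 5° pixels, 72 pixels wrapping
the full circle) in which a designated pixel product is forced to a
parity: for rightward stimuli, 2-point `s(x,t) = p·s(x−1,t−1)`;
converging 3-point `s(x,t) = p·s(x−1,t−1)·s(x,t−1)` (two early points,
one late); diverging 3-point `s(x,t) = p·s(x−1,t−1)·s(x−1,t)` (one
early, two late — the space-mirrored time reversal of the converging
rule). Glider conventions are usually stated pictorially, so the
package ships an
exhaustive audit (`audit_glider()`) that makes the implemented
convention machine-checkable. Leftward stimuli are spatial
reflections; the 60 detectors (5.1° apart) sit inside the periodic
360° stimulus, so there are no edge effects. Responses are averaged
over the last 2 s, over detectors, over 25 instantiations, pooled as
(right − left)/2, and normalized so the positive 2-point mean is 1.
The movie is rendered piecewise-constant in space and time before
photoreceptor filtering, like a display; the blur weights integrate
the Gaussian over each pixel by an 11-point sub-pixel quadrature.

## Problem sizes and degenerate inputs

The package's own test and example runs use desk-scale ensembles —
10⁴ mirror pairs, 200 synthetic images, 10⁶-sample pools for the
rank-transform statistics — chosen so the full suite runs on a single
CPU in minutes. At this scale the 1- and 4-predictor models are stable
(split SD < 0.01), while the 69- and 209-predictor polynomials
visibly overfit; their full-scale behavior requires the 5×10⁵-pair
ensembles that `emd_config(n_motions = 5e5)` will happily, if slowly,
produce. Degenerate inputs fail loudly rather than silently: all-zero
intensity images, empty pooled samples, zero-variance kurtosis, empty
penalty grids, and non-adjacent receptor pairs (unless explicitly
allowed — next-nearest correlators are legitimate components of the
6-channel model) all raise errors; an estimator with zero output
spread scales to the null estimator with a warning, and a glider table
whose normalizing response is zero is returned unnormalized with a
warning.

## Known limitations

* No photoreceptor adaptation, noise, or saturation; velocity is
  constant within a clip.
* No alternative temporal kernel families; the f/g pair is fixed.
* Behavioral dynamics (turning gain, motor delays) are out of scope —
  glider predictions are open-loop model outputs.
* The synthetic generator's sinh–arcsinh marginal cannot reach
  kurtosis below ≈2.6; sub-Gaussian image ensembles would need a
  different pointwise family.
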