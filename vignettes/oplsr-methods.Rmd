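---
title: "Selecting spectral variables with orthogonal PLS regression vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting spectral variables with orthogonal PLS regression vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spectral and omics matrices (NIR absorbances, LC–MS feature intensities,
NMR bins) routinely have far more variables than samples and strong
collinearity among variables. Ordinary regression is ill-posed there, and
per-variable testing ignores the joint structure. `oplsr` selects variables
associated with a response `Y` by combining three ingredients:

1. **Direct orthogonal signal correction (OSC).** The centered matrix `X`
   is split into a part orthogonal to the response and a corrected part.
   With `Ŷ = P_X Y` (the projection of `Y` onto the column space of `X`;
   for `p > n` with full row rank this is `Y` itself), the anti-projection
   `A_Ŷ X = X − Ŷ(ŶᵀŶ)⁻¹Ŷᵀ X` contains the response-orthogonal variation.
   Its leading principal component(s) give scores `t_osc` and loadings
   `p_osc`; the weight vector `r_osc = X⁺ t_osc` expresses the scores in
   terms of the original variables, and

   `X_orth = t_osc p_oscᵀ`, `X_osc = X − X r_osc p_oscᵀ`.

   Every orthogonal score satisfies `t_oscᵀY = 0` exactly, so
   `(X_osc)ᵀY = XᵀY`: the correction never touches the X–Y covariance.

2. **PLS with orthonormal scores.** PLS1 on `X_osc`: the first weight is
   the normalised covariance direction `X_oscᵀY / ‖X_oscᵀY‖`; scores are
   scaled to unit length, and later components are extracted after
   projection deflation of X (never of Y), keeping `tᵀt = I`. With
   orthonormal scores the latent regression estimate is simply `tᵀY`, and
   two regression vectors follow:

   `β_a = r Qᵀ` (against the corrected matrix, `Q = Yᵀt`), and
   `β_b = (I − r_osc p_oscᵀ) β_a` (against the original `X`), with
   `X β_b = X_osc β_a` identically. `β_b` accounts for each variable's
   role in both the predictive and the removed directions and is the
   default selection target.

3. **Permutation significance testing.** The sampling distribution of a
   PLS regression coefficient has no usable closed form. For each
   candidate variable the package builds an empirical null by shuffling
   the sample order within that variable's column of `X_osc`, refitting
   the PLS step, and recording the realised coefficient; the OSC weights
   are frozen (the correction is not refit), which is both the literal
   null of "this column carries no information given the fitted
   correction" and the reason the procedure is fast. Two-tailed p-values
   use the absolute-value count with the observed value included,
   `(count + 1)/(B + 1)`, so `1/(B + 1)` is the resolution floor.

A correlation pre-filter (level `alpha_f`) restricts the permutation test
to variables whose individual Pearson correlation with `Y` is significant
at `alpha_f` (two-sided t-test, `n − 2` df; for 0/1 labels this equals the
pooled two-sample t-test). This removes noise variables from the whole
procedure; `alpha_f` acts as the tolerance knob of the method.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha_f` | 0.05 | pre-filter level; controls how many variables enter the permutation test |
| `n_osc` | 1 | orthogonal components removed; one component usually absorbs the dominant baseline-like variation, and removing more risks eating predictive signal (1–3 supported) |
| `A` | 1 | predictive PLS components; on the bundled benchmark later components add almost nothing (1–3 supported) |
| `B` | 999 | null realisations per variable; with the `+1` convention gives p-value resolution 1/1000 |
| `subset_fraction` | 0.3 | fraction of candidates permuted jointly per refit; cuts the number of refits roughly threefold while leaving nulls close to normal |
| `alpha_pm` | 0.05 | selection level on permutation p-values; Bonferroni (`alpha_pm / n_tested`) optional, with the tested (filtered-in) count as the correction denominator |
| `scale` | FALSE | unit-variance column scaling; off because spectral signal is scale-dependent |
| `restrict` | TRUE | fit OSC/PLS on filtered-in columns only, so unfiltered noise cannot leak into the latent components; `FALSE` models the full matrix |

## Numerical choices

* Projections and pseudoinverses use rank-revealing SVDs with cutoff
  `max(n, p) · eps · σ_max`, which keeps `r_osc` stable on collinear data.
* Sign conventions: every weight/loading column is flipped so its
  largest-magnitude entry is positive, making output deterministic across
  platforms.
* Confidence intervals are empirical `(alpha_pm/2, 1 − alpha_pm/2)`
  percentiles with linear interpolation between order statistics
  (R quantile type 7). They are descriptive companions to the p-values;
  because the p-value is two-tailed in absolute value, a borderline
  coefficient over an asymmetric null can be selected yet sit just inside
  its interval.
* p-values are computed from exactly the first `B` realisations per
  variable (constant resolution); intervals use all retained realisations.
* Randomness is consumed in a fixed order (subset draw, then one sort key
  per cell of the chosen columns), so a seed fully reproduces a run.
* Degenerate inputs: constant columns get correlation p = 1 and can never
  be selected (dead detector channels pass through silently); a matrix
  whose columns are all proportional to `Y` has no response-orthogonal
  structure, and the correction degrades gracefully to the identity.

## The layered benchmark generator

`simulate_layers()` emulates multi-level collinearity: 9 individually
strong variables (4 high at label 0, 5 high at label 1), 21 group-wise
trivariate-normal variables whose labels separate jointly rather than
individually, and two aggregation layers in which every variable is split
into three children (`w_i (x + ε)`, weights from normalised uniforms drawn
once per parent, `ε ~ N(0, sd = |x|/10)` per sample), plus 610 standard
normal noise variables; labels are Bernoulli(0.4), `n = 40`, `p = 1000`.
The noise standard deviation is read as `|x|/10` (a variance of `x/10`
would be undefined for negative parents); the decomposition uses the
realised parent column, so each triple sums to its parent plus its noise
draw exactly.

What the generator does *not* emulate: instrument baselines and smooth
wavelength continuity (its orthogonal variation is isotropic noise plus
group structure, not a dominant low-rank baseline), heteroscedastic
measurement error, and class imbalance beyond the 0.4 label rate. Two
consequences matter when reading test results. First, because the
children inherit their parent's correlation with the response almost
undiluted (correlation is scale-free and ε is small), the aggregation
layers are genuinely response-associated, and *every* calibrated selector
— the permutation test and the FDR baseline alike — legitimately selects
many of them. Second, no rank-one matrix can dominate this X: the 610
isotropic noise columns bound the share of total sum of squares that the
single removed OSC component can carry to around ten percent (the whole
response-orthogonal subspace holds about 92%). On real spectra with a
dominant baseline the removed fraction is typically far higher; passing
tests on this generator therefore validates the algebra and the
calibration, not the magnitude of variance removed on any particular real
dataset.

## Design decisions

* The OSC correction is frozen during permutation: only the PLS step is
  refit on the permuted corrected matrix, and the frozen `r_osc`, `p_osc`
  convert refitted `β_a` into `β_b`.
* Restricted fitting (`restrict = TRUE`) is the default because the
  pre-filter exists precisely to keep noise variables out of the whole
  procedure; full-matrix fitting is one flag away.
* The FDR baseline uses the same correlation t-test as the pre-filter, so
  the two methods differ only in the selection mechanism, which is the
  comparison of interest.
* The lasso baseline is a fixed-penalty coordinate-descent fit (glmnet)
  with standardised columns and an unpenalised intercept; selection is
  the nonzero support. Regularisation-path tuning is out of scope.
* Multivariate responses (PLS2) and cross-validated choice of `A` are out
  of scope.

## Problem sizes used by the shipped tests

The packaged checks run the benchmark at 100 replicates (the full
protocol's layer-count table), 100 seeds for the variance decomposition,
200 replicates for null calibration, and 100 fuzzed shapes for the
algebraic identities; these sizes give Monte-Carlo standard errors well
below the asserted tolerances while keeping a complete run on a single
CPU comfortable. `scripts/acceptance.R` recomputes the variance-
decomposition summaries at 100 replicates by default (`--replicates`
raises it).

## Known limitations

* With `p ≫ n` and full row rank, `Ŷ = Y` exactly, so the anti-projection
  step reduces to projecting out the response direction itself; the
  "direct" correction then removes at most one response-orthogonal
  principal direction per component, and its share of variance depends
  entirely on how low-rank the orthogonal variation is.
* Y-variance captured per PLS component is not guaranteed to be monotone
  across components (Y is never deflated); on random matrices small
  inversions occur in a few percent of fits.
* Permutation p-values are exchangeability-based: they are calibrated
  per-variable under the global null, but selection among pre-filtered
  variables inherits the filter's selection effect, as in any two-stage
  procedure. Type-I calibration statements in the tests therefore use an
  inactive filter.
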