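---
title: "Estimating neighborhood population density from multispectral imagery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating neighborhood population density from multispectral imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdensat)
```

## The problem and the model

In rapidly growing cities with stale census data, neighborhood
("section") populations must often be estimated from a handful of
surveyed sections plus freely available satellite imagery. This package
implements a pipeline for that setting: from a 6-band surface-reflectance
raster (Thematic-Mapper-style bands 1, 2, 3, 4, 5 and 7 at 30 m; the
thermal band is excluded) and a per-section pixel mask, it constructs a
large catalogue of candidate covariates per section, and then searches
linear models of the transformed population density

$$\sqrt{d_i} = \beta_0 + \sum_{j \in M} \beta_j x_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $d_i$ is persons per km² of section $i$ and $M$ ranges over subsets
of the candidate covariates. The square-root response is the default
because it linearizes the density–reflectance relationship better than
the identity or log transforms on this kind of data; both alternatives
remain available (`transform = "ln"` / `"identity"`) so the comparison
can be reproduced. Populations follow from densities by
$\hat p_i = \mathrm{Area}_i \times \hat d_i$, with
$\mathrm{Area}_i = NP_i \times 900\,\mathrm{m}^2 \times 10^{-6}$ from the
in-mask pixel count.

The key assumption throughout is within-section homogeneity: a section's
density is summarized by section-level pixel statistics, with no spatial
disaggregation below the section. The optional NDVI mask
(`ndvi_mask()`, off by default) relaxes this slightly by removing
strongly vegetated pixels — NDVI $=(b_4-b_3)/(b_4+b_3)$ above a
threshold — before covariates are computed.

## The covariate catalogue

`build_covariate_table()` produces 379 named columns per section:

* **75 non-spectral transforms** — per-band moments of the raw
  reflectance (mean `b_i`, SD `b_is`, variance `b_iv`, CV `b_ic`), the
  squares `s_i = b_i^2`, and over the 15 band pairs the cross products
  `p_ij`, ratios `r.re_ij`, and difference-to-sum ratios `d_ij`, all
  computed from the six section-level band means;
* **304 spectral (pixel-level) transforms** — moments of the min–max
  normalized bands (`nb..`), and the four moments of per-pixel band
  ratios (`r_sp..`), difference-to-sum ratios (`ds..`; `ds` over bands 4
  and 3 is per-pixel NDVI up to sign/ordering), and hue transforms over
  the 20 band triples (`ch..` cylindrical, `rh..` rectangular).

Conventions that the data do not determine were fixed once and are
documented here:

* **Sample denominators.** SD and variance use $n-1$ denominators
  everywhere; one constant in the covariate engine governs it.
* **Normalization scope.** Min–max normalization is per section by
  default (`norm_scope = "section"`), since per-section rescaled grids
  are the natural display of a section's pixels; `"global"` normalizes
  against the union range of all sections, for users who want
  between-section brightness levels preserved in the `nb` family.
* **Hue formulas.** The band triple $(i,j,k)$, $i<j<k$, maps to
  $(R,G,B)$ in that order. Cylindrical hue is
  $\mathrm{atan2}(\sqrt3 (G-B),\, 2R-G-B)$ wrapped to $[0, 2\pi)$;
  rectangular hue is $(2R-G-B) / (2(R+G+B))$. Moments of hue are linear,
  not circular. Both formulas are pluggable (`hue_funs =`) so an
  alternative convention can be dropped in without touching callers.
* **Degenerate pixels.** Zero-denominator pixels (ratios, rectangular
  hue) and achromatic pixels ($R=G=B$, undefined hue) are excluded
  per-statistic, never imputed; exclusion counts are attached to the
  result. A zero mean makes a CV undefined; it is flagged `NA` rather
  than infinite. Constant bands min–max-normalize to zeros with a
  warning.
* **Masks are binary.** A pixel is wholly in or out of a section; there
  is no sub-pixel area weighting, consistent with the pure pixel-count
  area formula.

## Reduction and model search

With tens of sections and hundreds of candidates, exhaustive model
comparison is impossible and many covariates are algebraic near-copies
of each other. Two reduction stages precede the search:

1. an optional restriction to the 304 spectral transforms
   (`subset = "spectral"`, the pipeline default), and
2. `correlation_filter()`: walking the stable column order left to
   right, a column is dropped when its Pearson correlation with an
   already-kept column reaches the threshold (default 0.99, signed; an
   `absolute` flag is available). Keeping the *earlier* member makes the
   filter deterministic; the alternative (keeping the later member) is
   an arbitrary mirror of the same rule.

The search itself is MC3: a Metropolis–Hastings random walk over
inclusion vectors. Each step toggles one uniformly chosen covariate, or
with probability `swap_prob` exchanges an included for an excluded one;
both proposals are symmetric, so the acceptance ratio is the posterior
ratio. Under a Zellner g-prior on the slopes (intercept unpenalized,
response centered) the marginal likelihood of a model with $k$
covariates and fit $R^2$ is closed-form:

$$\log \mathrm{ML}(M) = \tfrac{n-1-k}{2}\log(1+g)
  - \tfrac{n-1}{2}\log\!\big(1+g(1-R^2_M)\big) + \text{const},$$

with the null model at 0. `g = "uip"` (unit information, $g=n$) is the
default; `g = "ebl"` estimates $g_M = \max(0, F_M - 1)$ per model from
its F statistic (empirical Bayes local — it peeks at the data, and is
provided as the benchmark variant, not the default). Three model priors
are available: uniform over models (default), independent-inclusion
binomial($\theta$), and beta-binomial with a prior expected model size.

Numerical and bookkeeping choices:

* $k_{\max} = n - 3$ by default, so $R^2$ and the marginal likelihood
  stay defined; proposals beyond it auto-reject, as do rank-deficient
  designs (scored $-\infty$).
* The ledger keeps the $K$ (default 1000) best-scoring distinct models
  seen anywhere in the chain, ranked by log posterior with a
  deterministic lexicographic tie-break on the inclusion vector.
  Posterior model probabilities are analytic (normalized over the
  ledger), so they do not depend on chain length once the ledger's
  membership stabilizes; visit counts and frequency-based inclusion
  probabilities come from the post-burn-in chain (burn-in defaults to
  10%). `convergence_corr()` correlates the two — values near 1 indicate
  the chain has equilibrated over the retained models.
* Everything is reproducible from one seed.

**A caution on the uniform model prior.** When the candidate count $p$
vastly exceeds $n$, the uniform-over-models prior concentrates posterior
mass in the enormous *number* of mediocre mid-sized models rather than in
a sharp sparse truth; the chain then drifts to large models even when a
small model has a far higher individual marginal likelihood. This is a
property of the posterior, not a sampler defect. The uniform prior
remains the default for fidelity to standard practice on
moderate-$p$ problems, but for sparse-recovery use (including the
package's own recovery tests, which run at $p \approx 250$, $n = 40$)
the beta-binomial prior with a small expected model size
(`prior_spec(model_prior = "binomial-beta", msize = 3)`) plus swap moves
(`swap_prob = 0.25`) is the recommended configuration.

## Refit, back-transform, evaluation

The selected model is refit by ordinary least squares (`ols_fit()`),
reporting classical SEs, $R^2$, and variance inflation factors
$\mathrm{VIF}_j = 1/(1-R^2_j)$. Predictions carry 95% confidence
intervals for the mean response by default (prediction intervals behind
a flag), and estimate and endpoints are back-transformed endpoint-wise
with no smearing correction: squaring for `sqrt` (negative predictions
are clipped to zero first and logged — real fits never produce them, but
synthetic extremes can), exponentiation for `ln`.

Evaluation uses the signed relative (proportional) error
$\mathrm{RE} = (\hat d - d)/d \times 100\%$, with summaries over absolute
values (the median of an even count is the midpoint of the two central
values). `loocv()` implements leave-one-out cross-validation with the
covariate set *frozen*: each fold re-estimates coefficients only and
predicts the omitted section on both scales. A stricter variant that
re-runs the whole MC3 search inside every fold is available
(`research = TRUE`) but is not the reference protocol. Folds that become
rank-deficient are flagged and excluded from summaries with a warning.

## The synthetic scene generator

No satellite scene ships with the package, so `generate_scene()`
produces section rasters with the statistical structure the analysis
assumes, and `generate_truth()` attaches populations from a known sparse
model on the $\sqrt d$ scale (non-positive draws are redrawn, since
densities are strictly positive, and the redraws logged). Design of the
generator:

* **Irregular masks** come from thresholding a smoothed Gaussian random
  field with a radial bias: compact blobs with ragged boundaries,
  300–2,600 pixels by default (the size range of real urban sections at
  30 m).
* **Spatially clustered cover classes.** A second smoothed field is
  thresholded to split each section into vegetation, built and bare
  cover (built fraction uniform on 0.15–0.90 by default; 15% of the
  built area is bare ground). Clustered — not i.i.d. salt-and-pepper —
  labels keep the texture statistics non-degenerate.
* **Class spectra** default to a vegetation profile (dark visible bands,
  bright near-infrared) and a brighter built/bare profile with strong
  shortwave-infrared response, with correlated within-class reflectance
  across bands (common correlation 0.6) plus i.i.d. sensor noise,
  clamped to (0, 1).
* **Per-section heterogeneity.** Each section shifts its class mean
  spectra band-by-band (`spectral_jitter_sd = 0.03` reflectance units)
  and scales its within-class spread by a per-band lognormal factor
  (`texture_jitter = 0.4` on the log scale). This matters statistically,
  not just cosmetically: every covariate here is a pixel-permutation-
  invariant moment, so without band-specific heterogeneity the whole
  catalogue would be driven by the single built-fraction factor, every
  covariate would be near-collinear with every other, and no sparse
  generating model would be identifiable — by any method. The default
  jitter is the smallest round value at which a band's normalized level
  and spread vary independently enough for the moment families to be
  distinguished at the recovery tests' sample size.
* **Default truth model**: $\sqrt d = -35 + 210\,\mathrm{nb7} +
  80\,\mathrm{nb4s} + \varepsilon$, residual SD 2 — one brightness
  covariate (normalized SWIR-2 mean, a built-up signal) and one texture
  covariate (NIR spread), both of which are first-in-order
  representatives of their correlation groups and therefore survive the
  0.99 filter; implied densities span roughly 700–13,000 persons/km²,
  matching the surveyed range of a West African city. A truth covariate
  that the documented filter itself removes (e.g. the mean
  difference-to-sum ratio of bands 3 and 4, a near-exact monotone
  transform of earlier columns) would make recovery ill-posed by
  construction, so such names are avoided in the default.

What the generator does *not* emulate: atmospheric-correction residuals,
cloud/shadow/water artifacts, mixed pixels at class boundaries, spatial
autocorrelation of the *noise*, non-homogeneous within-section density
(every section's density is one number), and any real geography.
Passing recovery tests on this generator therefore demonstrates the
correctness and calibration of the machinery, not field accuracy on real
imagery.

## Problem sizes used by the tests

The test-suite defaults were chosen to exercise each property at the
smallest size where it is statistically meaningful: enumeration checks
use $p = 8$ candidates and chains of 40–60k iterations; the end-to-end
recovery test uses 40 sections, residual SD 0.25, and a 100k-iteration
chain; pipeline smoke tests use 8–12 sections of 100–300 pixels with
2–4k iterations. The quadrature oracle for the g-prior marginal
likelihood integrates the three-dimensional integrand (intercept, slope,
log variance) by nested adaptive quadrature at $n = 12$ and matches the
closed form to $10^{-6}$.

## Known limitations

* With ~20 sections the search can and does find alternative models
  whose fit is statistically indistinguishable from the top model;
  inclusion probabilities, not the identity of the single best model,
  are the stable output.
* g-prior Bayes factors at small $n$ separate models only when their
  $R^2$ differ materially; near-duplicate covariates (e.g. an SD and
  the matching CV) share inclusion mass, which is visible as pairs of
  middling PIPs.
* Back-transformed confidence intervals are endpoint-transformed, so
  they are intervals for the transformed mean response mapped to the
  density scale, not exact intervals for the mean density.
* The raster reader expects the package's own multi-page float TIFF
  layout (band pages plus a trailing 0/1 mask page); georeferencing
  metadata is not interpreted.
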