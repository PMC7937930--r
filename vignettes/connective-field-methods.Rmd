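---
title: "Connective field modeling: methods, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connective field modeling: methods, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confield)
```

## The model

A connective field (CF) describes the activity of a target cortical vertex
as a spatially weighted aggregate of activity in a source region. With
source series $s_j(t)$ and a center vertex $c$ in the source region, the
predicted target time course is

$$p(t) = \sum_j w_j\, s_j(t), \qquad
  w_j \propto \exp\!\left(-\frac{d(j, c)^2}{2\sigma^2}\right),$$

where $d(j, c)$ is the geodesic distance along the cortical surface mesh
and $\sigma$ (mm) is the CF size. The measured target series is modeled as
$y(t) = \beta\, p(t) + \varepsilon(t)$ with Gaussian noise; $\beta$ is the
amplitude scaling ("effect size") of the predictor. Model quality is
summarized as variance explained, $\mathrm{VE} = 1 - \mathrm{RSS} /
\mathrm{TSS}$, with sums of squares about zero because all series are
centered by preprocessing.

Geodesic distance is the shortest path on the mesh edge graph (Dijkstra)
with 3D Euclidean edge lengths. Exact polyhedral geodesics are out of
scope; the distance backend sits behind `geodesic_distances()` so a more
accurate backend could be substituted without touching the fitters.
Distances are cached per center vertex, and repeated queries return
identical values. Vertex ids are 1-based everywhere in the package — the
natural convention for R and igraph — and the file readers translate from
the 0-based conventions of GIFTI and FreeSurfer files on the way in and
out.

Kernel weights are normalized to unit sum by default, so that $\beta$
reads directly as signal amplitude scaling; unit-maximum normalization is
available (`cf_kernel(..., normalize = "max")`) because the original
implementations are ambiguous on this point. The choice only rescales
$\beta$; center, $\sigma$, and VE are unaffected.

## Standard (grid) fitting

`fit_cf_grid()` searches every source vertex crossed with a log-spaced
$\sigma$ grid (default 0.5–25 mm, 24 points), fitting $\beta$ by
no-intercept OLS and retaining the maximal-VE model. Ties are broken
toward the smaller $\sigma$ and then the lower vertex id, making the fit
fully deterministic. The log spacing reflects the multiplicative nature of
plausible CF sizes: resolution is finest where small absolute differences
matter.

## Bayesian fitting

`sample_posterior()` runs a random-walk Metropolis–Hastings chain over
$(c, \sigma, \beta)$, by default 15000 iterations with the first 10%
discarded as burn-in. Design choices:

* **Likelihood.** The Gaussian noise variance is profiled out, giving
  $\log L = -\tfrac{T}{2}\log \mathrm{RSS}$ up to constants — identical in
  shape to marginalizing the variance under a Jeffreys prior. This keeps
  the chain three-dimensional.
* **Priors.** Uniform over source vertices; log-uniform $\sigma$ on
  [0.3, 40] mm; uniform $\beta$ on $[0, \beta_{\max}]$ with
  $\beta_{\max}$ ten times the OLS amplitude of the ROI-mean predictor.
  Weakly informative, covering the grid fitter's range.
* **Proposals.** The center moves uniformly within its k-ring mesh
  neighborhood (k = 2) with a 5% chance of a global jump for mixing; the
  neighborhood proposal is asymmetric at region boundaries, so the
  Hastings ratio includes the neighborhood cardinalities. $\sigma$ takes
  Gaussian steps on the log scale (step 0.15); $\beta$ takes Gaussian
  steps scaled to the OLS amplitude. Every tuning constant is exposed in
  `cf_mcmc_config()`.
* **Point estimate.** The highest-posterior visited sample (MAP) by
  default; posterior mean by configuration. The upstream tools do not
  state which form they report, so both are provided.
* **Uncertainty.** Q3 − Q1 of each post-burn-in marginal, with type-7
  (linear interpolation) quantiles. It is nonnegative by construction and
  zero for degenerate (point-mass) posteriors.

These sampler internals are this package's own design: they are simple,
irreducible and aperiodic on the discrete–continuous product space, but
they are stand-ins, not a replica of any particular Matlab implementation.
Correctness is established behaviorally: the MAP agrees with exhaustive
maximization of the same log-posterior on small instances, chains are
bit-reproducible under a fixed seed, and the 50% credible interval for
$\sigma$ covers the generating value at its nominal rate on synthetic
data (the coverage test in the acceptance battery).

Acceptance rates outside [1%, 95%] trigger a tuning warning, never an
error: on noiseless data the likelihood is razor-sharp and the chain
freezes at the mode, which is expected rather than pathological.

## Preprocessing

Resting-state-like series are band-limited to 0.01–0.1 Hz before fitting:
a discrete cosine transform (DCT) high-pass at 0.01 Hz followed by a
zero-phase 4th-order Butterworth low-pass at 0.1 Hz, applied identically
to source and target series.

* The DCT high-pass regresses out the orthonormal basis of cosines with
  frequency below the cutoff, including the constant. A pure linear drift
  is *not* exactly representable by finitely many cosines (its cosine
  coefficients decay as $1/k^2$, leaving a residual correlation of about
  0.008 at 350 volumes), so the nuisance basis additionally includes a
  linear trend column by default (`include_trend = TRUE`) — standard fMRI
  detrending practice, and it makes drift removal exact. The projection
  is idempotent and its output exactly orthogonal to the removed basis.
* The Butterworth filter is designed by bilinear transform with frequency
  prewarping (coefficients identical to the reference scipy design) and
  applied forward–backward. Zero-phase filtering avoids phase distortion
  that would bias CF estimates; whether the original analysis was
  zero-phase is unstated, so this is recorded as a config-visible
  decision. The forward–backward pass squares the magnitude response: a
  0.2 Hz probe at TR 2 s is attenuated well below the single-pass analog
  value $(1+2^8)^{-1/2} \approx 0.062$.
* `percent_signal_change()` (100·(x−mean)/mean) is provided for
  raw-intensity inputs; synthetic series are generated zero-mean and unit
  variance and skip it.

## Surrogate null and the FWE beta threshold

To threshold voxels by effect size rather than VE, the null distribution
of $\beta$ under "no specific coupling" is built with iterative
amplitude-adjusted Fourier transform (IAAFT) surrogates: each source
series is replaced by a surrogate with exactly the original value
distribution and near-exactly the original amplitude spectrum, but
randomized temporal alignment. The target series stay untouched, the CF
model is refit with the surrogate predictors by the same procedure used
for the real data, and the best-fit betas are pooled across the target
region. The threshold is the 95th percentile (type-7) of that pooled
null. The surrogate side is configurable (`n_realizations`) because one
surrogate per vertex gives a small pool whose 95th percentile is noisy;
more realizations tighten it.

How exact is "near-exactly"? The IAAFT fixed point at 350 timepoints has
a relative RMS amplitude-spectrum discrepancy of about 1% for broadband
series and 1–3% for 0.01–0.1 Hz band-limited series; this is a
structural property of the iteration (a series with *exactly* the
original's values and spectrum exists only as a circular shift or
reflection of the original, which would not be a randomized surrogate),
reproduced identically by an independent reference implementation. The
value distribution, by contrast, is exact: the final step is a rank
reordering of the original's sorted values.

Two readings in the source material are resolved as follows: "95% CI"
and "95th percentile" are treated as the same pooled-percentile rule; and
the pooled rule controls the *per-voxel* error rate, not familywise error
in the max-statistic sense — a stricter max-statistic variant can be
obtained by thresholding at the maximum of the pooled null
(`fwe_beta_threshold(null, 100)`). Degenerate fits with $\sigma \approx
0$ can be excluded before thresholding comparisons
(`select_voxels(discard_sigma_below = )`).

Calibration of the rule is tested where it can be exact: with spatially
*uncorrelated* sources, surrogate predictors are exchangeable with the
real ones, and the retention rate under the $\beta = 0$ regime matches
the nominal 5% within Monte-Carlo error. With spatially correlated
sources, per-vertex surrogates destroy the cross-vertex correlation and
the threshold becomes conservative — consistent with the original
report's observation that the threshold "proved to be more conservative"
than VE thresholding.

## Visuotopic back-projection and map filters

A fitted CF center is a cortical location; its visual-field coordinates
are inherited from the population receptive field (pRF) of that center
vertex: eccentricity $\sqrt{x_0^2+y_0^2}$ and polar angle
$\mathrm{atan2}(y_0, x_0)$ (radians internally, counterclockwise from the
positive horizontal meridian). Map-level analyses retain vertices with VE
> 0.15 and back-projected eccentricity within [1°, 7°], bounds
inclusive. The eccentricity clause in the source description ("<1° and
>7° were included") is grammatically impossible; it is implemented as
*excluding* eccentricities outside [1°, 7°], consistent with trimming
foveal and peripheral map edges under a 10.2° stimulus radius. Whether
the filter applies to pRF-derived or CF-derived eccentricity is also
unstated; the CF-derived (back-projected) value is used and the choice is
switchable by passing a different eccentricity vector.

## Reliability battery

* Pearson r with two-sided p (eccentricity, CF size, beta); zero-variance
  inputs are flagged NA rather than silently zero.
* Fisher–Lee circular correlation for polar angle, with a seeded
  permutation p-value (1000 permutations) rather than the asymptotic
  approximation; it is invariant to separate rotations of either angle
  set.
* Coefficient of variation sd/|mean| (sample sd) across repeated scans.
* ICC between two scans from the two-way ANOVA decomposition. The
  upstream citation does not name a Shrout–Fleiss form; ICC(3,1) —
  two-way mixed, consistency, single measure — is the default for
  test–retest of continuous maps, ICC(2,1) is selectable, and the report
  names the variant. The ICC is evaluated on the strongest-VE fraction of
  voxels (default 5%, sweepable over {1, 5, 10, 25, 50}%).
* CF size vs eccentricity: eccentricities binned at 1°, OLS on the bin
  means, and a 95% percentile bootstrap (1000 replicates, resampling
  vertices within bins) for the confidence band of the fit.

Group-level use concatenates per-participant values; a
per-participant-then-summarize mode is a matter of applying the same
functions per participant and aggregating, which the API leaves to the
caller.

## The synthetic world

The generator stands in for non-deposited scanner data, so its defaults
are the stated acquisition: two scans of 350 volumes at TR 2 s in the
0.01–0.1 Hz band, a source region of 400 vertices and a target strip of
100 vertices on a regularly triangulated patch (1.5 mm spacing, about the
cortical sampling pitch of a 3 T voxel grid). Eccentricity runs
log-linearly along rows (cortical magnification), polar angle linearly
along columns; pRF sizes grow linearly with eccentricity and pRF VE is 1
(the map is exact by construction).

Source signals are spatially correlated, band-passed Gaussian noise:
white series mixed through a squared-exponential geodesic kernel (length
scale 3 mm by default), Fourier-masked to the band, then z-scored. CF
estimation depends only on second-order spatiotemporal structure, so no
hemodynamic forward model is simulated; an AR(1) switch exists for
robustness checks. Targets are generated by the CF model read forwards —
unit-sum geodesic Gaussian kernel, true $\beta$, white Gaussian noise.
No signal-to-noise figure is reported for the real 3 T data; the default
$\beta = 1$, noise sd 1 places fitted VE around the 0.15 working
threshold, which is the regime the thresholding analyses operate in.
True $\sigma$ values default to interior points of the fitting grid so
that noiseless recovery is exact (the generative-inversion test).

What a green test does **not** establish: the generator has no
hemodynamic response, no physiological or motion artifacts, no
vascular/spatial noise correlations on the target side, and a flat,
regular mesh rather than folded cortex. Tests on it validate the
*estimators* (inversion, calibration, determinism), not the empirical
claims about real 3 T data.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation) throughout.
* RSS is floored at $10^{-12}\,\mathrm{TSS}$ inside the log-likelihood so
  noiseless data cannot produce $-\infty$/overflow; the MAP is unaffected.
* IAAFT converges when the relative RMS spectral discrepancy changes by
  less than $10^{-8}$ (default) or at 1000 iterations; constant series
  are rejected (degenerate spectrum).
* Grid-fit ties: smaller $\sigma$, then lower vertex id.
* Disconnected source regions, overlapping source/target regions, empty
  labels, zero predictors, and zero-variance correlation inputs all raise
  immediate, named errors rather than propagating NaN.
* Every stochastic stage derives its seed deterministically from the
  master seed (`seed`), so whole pipelines are byte-reproducible and any
  stage can be re-run in isolation.

## Known limitations

* Dijkstra path lengths overestimate true surface geodesics on coarse
  meshes (metrication error); fine for model fitting, but absolute
  $\sigma$ values inherit the mesh resolution.
* The Bayesian sampler is single-chain; convergence is monitored only via
  acceptance rates and reproducibility checks, per the intended scope.
* NIfTI volume I/O is not provided (no NIfTI reader in the supported
  dependency set); per-vertex series exchange as tab-delimited text.
* The pooled-percentile "FWE" rule is per-voxel in the strict sense; see
  the surrogate section for the stricter alternative.
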