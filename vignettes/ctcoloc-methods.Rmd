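---
title: "Methods: colocalizing lifespan cortical thickness change with neurobiological markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalizing lifespan cortical thickness change with neurobiological markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcoloc)
```

## The statistical problem

All analyses in `ctcoloc` operate on *parcellated brain maps*: one
scalar per cortical parcel (148 regions in the Destrieux convention, 74
per hemisphere). The scientific question — do the spatial patterns of
cortical thickness (CT) change align with the cortical distributions of
receptors, cell types, or microstructure? — reduces to correlating or
regressing one map on others across parcels. Two features make naive
inference invalid:

1. **The sample size is arbitrary.** The number of parcels is a choice
   of parcellation, not a number of independent observations.
2. **Brain maps are spatially autocorrelated.** Neighboring parcels are
   alike, so the effective degrees of freedom are far below the parcel
   count, and parametric p-values are anticonservative.

The package therefore treats effect sizes (Spearman rho, R², dominance)
as the interpretable quantities and derives **all** p-values
empirically, by re-running the identical analysis with surrogate
predictor maps that preserve each predictor's spatial autocorrelation
but randomize its alignment with the outcome.

## Relative CT change and the window scheme

Given normative CT trajectories (modeled CT per parcel, age, percentile,
sex), relative change between ages $i$ and $j$ is

$$\Delta\mathrm{CT}_{(i,j)} = \frac{\mathrm{CT}_j - \mathrm{CT}_i}{\mathrm{CT}_i}$$

per parcel, computed on the median (50th percentile) sex-average slice
by default (sex-average = mean of female and male CT *before* the
ratio). The lifespan scheme slides a 5-year window in 1-year steps from
age 5 to 90 (81 windows), optionally appending the whole developmental
period $\Delta(5,30)$ (82 windows). Window endpoints must lie on the age
grid — there is no interpolation, because the normative model is
extracted on a fixed 0.5-year grid (171 points from 5 to 90). Windows
are labeled by their midpoint for reporting (e.g. $\Delta(5,10)$ at
7.5 years); all arithmetic uses the endpoints. Sensitivity knobs: window
lengths 1 or 2 years, alternative percentiles and sexes, and a
baseline-CT correction mode that residualizes $\Delta$CT on the
window's baseline CT across parcels before modeling.

## Variogram-matched surrogate maps

Surrogates are generated per predictor map with a permute-and-smooth
construction: (i) randomly permute the map across parcels, destroying
all spatial structure; (ii) smooth the permutation with
k-nearest-neighbor kernels (exponential decay, bandwidth = distance to
the k-th neighbor) over a ladder of scales (10 log-spaced rungs from
k = 2 to half the parcels); (iii) pick the scale and the affine
recombination of smoothed map + white noise whose variogram best matches
the source map's, by least squares; (iv) restore the source's exact
value distribution by rank mapping (so every surrogate has the source's
value multiset, hence its exact mean and SD).

Two variogram estimators coexist deliberately. The *descriptive*
estimator (`empirical_variogram`) is the classical binned semivariance
$\gamma(h) = \tfrac12\,\overline{(x_u - x_v)^2}$ over equal-count
distance bins. For *fitting and quality control* the package uses a
Gaussian-kernel-smoothed variogram (25 evaluation points, bandwidth
three times their spacing) truncated at a pair-distance quantile.
Smoothing matters because binned variograms at 148 parcels are noisy —
we measured that even two independent draws of the *same* Gaussian
process have binned full-range variograms that rank-correlate at only
~0.4. The truncation default matters too, and was set by calibration,
not convenience: fitting only the short range (25th percentile of
distances) lets surrogates carry long-range structure the fit cannot
see, which inflates null R² against smooth outcomes and biases
empirical p-values conservative (type-I error ~0.02 for some source
maps). Fitting out to the *median* pairwise distance (the package
default, `dist_quantile = 0.5`) removes that bias: across replicate
source maps, null-calibration KS tests and 5%-level type-I rates sit at
their nominal values. Quality control (`variogram_match_quality`)
reports surrogate-to-source variogram Spearman correlations — median
~0.98 for processes with a correlation length near 30% of the map
extent — and surrogate-to-source *map* correlations, which center on
zero.

One ensemble per atlas is generated once (seeded, reproducible) and
reused across every window and analysis; production default is 10,000
surrogates, tests use 99–1,000.

Empirical p-values use the $(k+1)/(N+1)$ convention, one-sided, ties
counting against the observation — a valid (never anticonservative)
finite-sample estimator whose minimum is $1/(N+1)$, never 0. BH-FDR is
applied within declared families: univariate scans within each source
modality, multivariate scans across all models and modalities, dominance
scans as one family spanning the full-model and all predictor-wise
tests (82 + 82 × 9 p-values in the canonical lifespan run).

**Calibration is the load-bearing property.** For GP-simulated change
maps independent of the atlases, univariate empirical p-values are
uniform (KS test) with type-I error at the nominal 5% level; this is
asserted in the test suite (500 replicates against a 1,000-surrogate
ensemble) and recomputed by `scripts/acceptance.R`.

## Explained variance and dominance

Univariate scans regress each window's change map on one atlas; the R²
equals the squared Pearson correlation (asserted to 1e-12). Multivariate
scans fit OLS with all predictors (z-scored, intercept included; change
maps left in native units) and report adjusted R²; null iterations redraw
*one surrogate per predictor jointly*, so the null preserves the
predictor set's autocorrelation while breaking its alignment with the
outcome. Negative adjusted R² values are reported as computed, not
clipped.

Total dominance decomposes the full-model R²: for predictor $x$, average
over subset sizes $k$ the mean incremental R² of adding $x$ to every
size-$k$ subset not containing it. The package enumerates all $2^p$
subsets exactly (hard cap p = 15, error beyond) — no bootstrap or
sampling approximation — which makes the decomposition testable against
an independent oracle (the average of incremental R² over all $p!$
predictor orderings), to 1e-10. Plain R² is used inside the
decomposition because additivity (contributions sum to the full-model
R²) holds only for the unadjusted statistic; adjusted R² is reported for
the full model alongside. Regional influence maps difference the
absolute residuals: $\Delta PE = |PE_{X \setminus \{x\}}| - |PE_X|$ per
parcel, positive where predictor $x$ improves the fit. (Descriptions of
this statistic sometimes speak of excluding *regions*; the implemented
formula excludes a *predictor* and maps the per-region residual
difference, which is the formula-level definition.)

## Factor-level markers

Atlas libraries are reduced per modality (nuclear imaging vs. cell-type
expression; the lone microstructural map passes through unreduced as
`mr1`). Extraction is minimum-residual (unweighted least squares) common
factoring of the atlas correlation matrix, implemented in-package as a
quasi-Newton optimization over uniquenesses (objective: sum of squared
discarded eigenvalues; start: 1 − squared multiple correlations;
convergence 1e-6, max 1,000 iterations), since no installed package
provides ULS extraction; ML `factanal` on a clean simulated structure
serves as an independent cross-check in the tests. Retention keeps every
unrotated factor whose SS-loading share of *total* variable variance is
≥ 1% (whether the criterion should use total or common variance is
genuinely open; total is implemented and flagged). Rotation is promax
(κ = 4) on a varimax pre-rotation; factor scores use the regression
(Thurstone) method and are z-scored across parcels; each factor is
oriented so its top-loading atlas loads positively; an atlas tied across
factors is assigned to the lower-index factor. Rotated variance shares
are SS of *structure* loadings / number of maps — for oblique solutions
these overlap, so the cumulative value is reported with that caveat.

The permuted-map validation refits the identical pipeline on libraries
whose parcel order is independently permuted within each map and
compares cumulative rotated variance (one-sided empirical p). Permuted
refits retaining zero factors contribute a null value of 0.

## What the synthetic generators emulate — and what they do not

- `make_parcel_geometry`: centroids on two mirrored spherical caps
  (Fibonacci lattice + seeded jitter, radius 50, gap 10). Captures
  hemispheric separation and quasi-uniform parcel spacing; it is not a
  cortical mesh, and distances are Euclidean, not geodesic.
- `sample_gp_map` / `make_atlas_library`: zero-mean Gaussian processes
  with exponential covariance $\exp(-d/\ell)$ (default
  $\ell = 15 \approx$ 3 inter-parcel spacings), equicorrelated across
  maps via a shared latent map (default cross-correlation 0.3, matching
  a moderately collinear atlas library). The exponential kernel is the
  family the variogram surrogates assume, which keeps calibration tests
  interpretable.
- `make_ct_trajectories`: CT = baseline map (≈2.5 mm, mild spatial
  variation) × declining age factor × (1 + m·ramp), with the ramp rising
  smoothly across a designated target window. The window's relative
  change is thereby an affine image of the modulation map m = designed
  atlas mixture + GP noise, the noise orthogonalized against the signal
  so the realized construction R² equals var(signal)/var(total) exactly.
  Percentile curves are multiplicative offsets; sex curves are
  symmetric age-dependent offsets whose average is exactly the median
  curve. CT stays positive by construction. Not emulated: percentile
  crossing, site effects in the normative model, age-varying spatial
  patterns outside the target window.
- `make_expression_dataset`: 33 subjects by default, ages
  0.33–82.05 years uniform on the square-root scale (dense in childhood,
  several adults — the sampling profile of postnatal brain-development
  expression resources), signal genes elevated by `effect_size`
  (within-gene SD units) inside a peak period with smooth logistic
  edges, flat brain genes, and a 2,154-gene non-brain null pool.
- `make_cohort`: per-subject CT = population trajectory at the session
  age + subject random-intercept GP map + site-offset GP map + i.i.d.
  noise, two sessions at ages 10 and 12 by default (baseline / 2-year
  follow-up). Subjects sit exactly on the nominal session ages; data are
  emitted already harmonized (no site × scale interactions), since site
  harmonization is out of scope.

Passing tests on these generators demonstrate that the *machinery* is
correct and calibrated under known ground truth; they do not establish
that real CT change is explained by real marker maps, nor do they probe
misspecification (non-exponential autocorrelation, geodesic geometry,
heteroscedastic noise, scanner artifacts).

## Gene-trajectory validation

For each marker, its gene set's expression is averaged per subject,
smoothed over age with LOESS (span 0.75, locally quadratic, tricube
weights — standard defaults, recorded in results; exact fits are
evaluated with `surface = "direct"` so the noiseless-polynomial identity
holds), and evaluated on a 0.5-year grid strictly inside the observed
age range (no extrapolation; postnatal subjects only). The statistics
are the curve's mean inside the marker's significant period, and the
inside/outside ratio — computed on the smoothed curve, not the raw
points. Null distributions re-run the identical pipeline on `n_null`
size-matched gene sets resampled from the non-brain pool (draws shared
across markers with equal set size and period); p-values are
positive-sided empirical, and BH-FDR spans all marker × statistic tests
as one family. The mean statistic is invariant to adding a constant to
all genes; the ratio is not — both behaviors are asserted.

## Single-subject transfer

Per-subject relative change maps use the same ΔCT formula; subjects
missing a session are excluded with a logged count. Each subject gets an
exhaustive dominance decomposition. Group-level inference tests the
cohort-*mean* full-model R² and each cohort-mean dominance against
`n_null` (default 1,000) re-analyses with surrogate predictor sets; one
surrogate set is shared across subjects within an iteration, because the
exchangeability argument lives on the atlases, not the subjects. The
cohort-average change map and the average of subject change maps differ
by the nonlinearity of ratios; both are available.

## Numerical choices and problem sizes

- Z-scoring uses the population SD (denominator n); the choice cancels
  in rank correlations and R².
- Missing parcel values are rejected, never imputed; cross-map
  operations refuse mismatched parcel orderings outright.
- GP sampling adds a 1e-8 nugget before Cholesky.
- Degenerate inputs (constant maps, rank-deficient designs, singular
  correlation matrices, empty null sets) raise errors naming the
  problem.
- The test suite and the acceptance script run at deliberately modest
  sizes chosen to exercise every property at full 148-parcel resolution:
  1,000-surrogate ensembles with 500 null replicates for calibration,
  50 replicates for mixture recovery, 1,000 null gene sets, 99-iteration
  group tests over 40 replicate cohorts. Production analyses would raise
  the surrogate and resampling counts to 10,000 without any code change.

## Known limitations

A structural limitation of all surrogate-map inference deserves
emphasis: the variogram pins down a map's isotropic second-order
structure, not its exact alignment with the smooth low-frequency
directions of the cortex. For a *fixed* atlas realization, surrogate
null distributions can therefore sit a few percent above or below the
observed statistic's true null distribution, and these per-map
deviations correlate across an intercorrelated library (they share the
common component), so conditional multivariate and group-level error
rates can deviate from nominal for a given library even though they are
correct on average over map realizations. Calibration simulations in
this package accordingly redraw the library across replicates; users
analyzing one fixed real library should read empirical p-values near
the threshold with that conditional variability in mind.


- Euclidean centroid distances stand in for geodesic cortical distances;
  one distance matrix spans both hemispheres (interhemispheric distances
  are large, so smoothing kernels act effectively within hemisphere).
- The surrogate generator assumes the variogram is informative at short
  range; maps with essentially no autocorrelation degenerate gracefully
  (the white-noise term dominates) but their "match" is then vacuous.
- Dominance analysis is exact but exponential in predictors (capped at
  p = 15).
- The factor-retention rule operates on total-variance shares; libraries
  whose structure lives in a small common-variance fraction may retain
  factors differently under a common-variance reading of the same rule.
- Whether marker atlases should be hemisphere-symmetric is left to the
  data: the containers track hemisphere labels but impose no symmetry.
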