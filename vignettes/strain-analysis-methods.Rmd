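---
title: "Spectral phenotyping of amyloid plaque strains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phenotyping of amyloid plaque strains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscope)
library(dplyr)
```

## The problem

Amyloid-beta (Aβ) aggregates into extracellular plaques whose fibrils can
adopt distinct, self-propagating conformations — *strains*. Conformation-
sensitive fluorescent dyes (curcumin, FSB, BF-188) shift their emission
spectra with the local packing of the bound amyloid, so a plaque's joint
three-dye emission signature is an in-situ proxy for its strain content.
`strainscope` implements the computational arm of this assay: from per-plaque
emission spectra (or spectral lambda-stack images) to a PCA strain space,
a kernel-density definition of *shared versus cohort-unique* strain
signatures, a variance-weighted RMSD heterogeneity statistic, and
cohort-level inference on patient centroids. The motivating comparison is
between Down-syndrome (DS) brains, sporadic Alzheimer's disease (AD), and
cognitively unimpaired donors with Alzheimer's neuropathologic change
(ADNC).

Because no raw spectra are publicly deposited for this assay, the package
ships a first-class synthetic-data generator that emulates the study's
structure with known ground truth; every downstream stage is validated
against that ground truth.

## Composite spectral vectors

Each plaque contributes one spectrum per dye on a common wavelength grid —
by default 40 channel centers evenly spaced on 385–780 nm (step ≈ 10.1 nm),
each representing a 15-nm-wide sliding detection window. The analysis text
sometimes describes the channels as "15 nm intervals"; the two readings
cannot both describe the spacing, and we treat 15 nm as the *window width*
with spacing fixed by 40 channels over the span. The grid is configurable
(`wavelength_grid()`).

Per plaque:

1. each dye's spectrum is linearly interpolated onto the grid
   (`resample_to_grid()`); spectra that do not cover the grid span are an
   error, not an extrapolation;
2. each dye block is divided by its own maximum (`normalize_max()`) —
   per-dye, not global, normalization, so each block's max is exactly 1.
   All-zero blocks (a dye that failed to bind) are retained and flagged
   rather than rejected; exclusion is a pipeline decision;
3. the three blocks are concatenated (`build_composite()`) into a
   length-120 vector in a dye order drawn **once per analysis run** from a
   seeded generator and applied to every plaque. A per-plaque random order
   would destroy the common coordinate system; a uniform order is an
   isometry, so all distances, PCA variances and downstream statistics are
   invariant to which order was drawn.

To avoid biasing the eigenspace toward heavily sampled patients, at most 30
vectors per patient are retained (`cap_vectors_per_patient()`), sampled
uniformly under a seed. `subsample_robustness_check()` refits the space
without the cap, under different cap seeds, and under minority-cohort
oversampling, and reports matched-component score correlations and MANOVA
agreement across runs.

## The strain space

`fit_strain_space()` performs mean-centered, unscaled PCA on the composite
vectors. Signs are fixed by making each component's largest-magnitude
loading positive, so fits are deterministic across platforms. PC1 is
excluded from all biological analyses by default: a mid-study microscope
recalibration introduced a smooth, wavelength-dependent gain difference
between acquisition batches, and that artifact dominates the first
component. The package's synthetic generator reproduces this: the batch
shift is a *multiplicative linear tilt* in wavelength (a constant gain
would be erased by max-normalization), and with a shift that is large
relative to the archetype differences, PC1 correlates with batch at
|r| > 0.9 while PCs 2–3 are nearly batch-free — which is exactly what
licenses dropping PC1.

Defaults, both configurable: eigenspace analyses (plots, centroids,
MANOVA) use PCs 2–3; the heterogeneity statistic uses PCs 2–4.

## Shared-region classification

For each reference cohort (ADNC and AD), a Gaussian kernel density estimate
is fitted on that cohort's plaque scores (`fit_density_region()`), with
full data covariance and Scott's bandwidth factor by default. The "99.5%
region" is the density super-level set whose threshold is the empirical
(1 − coverage) quantile of the reference points' own densities, so at
least ⌈0.995·N⌉ reference points lie inside by construction. Whether the
original analysis calibrated by reference quantile, by integrated
probability mass, or by a plotted contour is not stated; both calibrations
are implemented (`calibration = "quantile"` or `"mass"`) and quantile is
the default because it reproduces the observed behavior that more than 95%
of reference vectors fall inside their own region. Regions are fitted in
the PC2–PC3 plane; 30/60/90% contours at the same construction are
plotting aids only.

`classify_membership()` labels each query plaque `in_both`,
`in_ADNC_region`, `in_AD_region`, or `outside_both`. Plaques outside both
reference regions carry spectral signatures unrepresented in either
reference cohort — the operational definition of cohort-unique strains.

## The heterogeneity statistic

For retained components with explained-variance proportions
\(w_x, w_y, w_z\) (frozen from the fit onto each score set), the distance
of a point from a centroid is

\[ d_i = \sqrt{(x_i-\bar x)^2 w_x^2 + (y_i-\bar y)^2 w_y^2 +
   (z_i-\bar z)^2 w_z^2}, \]

and the heterogeneity of a set of \(N\) points about their centroid is

\[ \mathrm{RMSD} = \sqrt{\tfrac{1}{N-1}\sum_i d_i^2}. \]

The weights enter *squared* inside the distance, exactly as in the
defining equation, even though this makes each weight act linearly on its
coordinate's contribution — fidelity to the printed formula is preferred
over the plausible alternative of unsquared weights. The \(N-1\)
denominator is kept for cohorts as printed, including \(N = 2\); sets with
fewer than 2 points are reported as `NA`, never 0. Per-patient RMSD uses a
patient's plaque scores about the patient centroid; per-cohort RMSD uses
patient centroids about the cohort centroid.

## Cohort inference

MANOVA on patient centroids in PC2–PC3 uses Wilks' lambda
\(\Lambda = \det(E)/\det(E+H)\) with Rao's F approximation (exact for 2
groups or 2 dimensions), via `stats::manova()`. Perfect separation
(singular within-group scatter with nonsingular total scatter) returns
\(\Lambda = 0\) with a warning rather than an error. Covariate
associations use OLS of a centroid coordinate on a patient attribute with
Pearson r and a two-sided p (`centroid_covariate_regression()`), missing
covariates dropped pairwise; categorical attributes use rank tests
(Wilcoxon for 2 groups, Kruskal–Wallis beyond — the original analysis names
only a plot-annotation utility, whose default behavior these
distribution-free tests generalize). Nominal p-values are reported by
default, matching the source analysis; Benjamini–Hochberg adjustment is
available in `regression_grid()`.

## Pathology scoring

Frontal-cortex burden grades \(X_{A\beta}\) and \(X_{tau}\) (0–4) are
assigned from per-mm² densities averaged over scored fields. The published
rule rows are not an exhaustive partition (e.g. exactly 1 plaque with no
dense-cored plaques matches no row verbatim), so scoring evaluates each
row's *lower-bound* conditions and returns the highest satisfied grade —
the only monotone total extension — flagging counts that fall in a
boundary gap. Interval boundaries shared between adjacent tau rows (1–5,
5–12, 12–25, ≥25 NFTs) are half-open with the boundary belonging to the
higher grade, preserving monotonicity; this is a documented convention,
not an inference of the scorers' intent. Morphological filtering of what
counts as a "mature NFT" is an input-preparation responsibility.

`generate_pathology_counts()` inverts the rules from interior points of
each rule interval, so scoring its output round-trips to the requested
grades for all 25 grade pairs — the scoring stage's ground truth.

## The synthetic-data generator

`generate_archetypes()` draws latent strain archetypes: per dye, a smooth
nonnegative profile of 1–2 Gaussian peaks with archetype-specific centers.
Strain identity is a joint three-dye signature (no single dye need
separate two archetypes), and distinct archetypes always differ in at
least one dye's peak channel. An optional `blend` argument shrinks all
archetypes toward their common mean — the knob used to construct regimes
where the batch artifact dominates the biological signal.

`generate_cohort_dataset()` nests plaques in patients in cohorts. Default
study conditions: DS = 15, AD = 10, ADNC = 8 patients; 10–40 plaques per
patient (spanning the 30-vector cap from both sides); four archetypes of
which the fourth is DS-only at mixture weight 0.3; additive Gaussian noise
at 2% of profile peak; a batch gain tilt of ±30% across the spectrum for
half the patients; patient covariates (Aβ40, Aβ42, pTau) linear in the
patient's loading on the marker archetype plus Gaussian noise. Plaque-level
intensity scale is a lognormal per-patient brightness factor (sdlog 0.3) —
the intensity distribution of real plaques is not documented anywhere, so
this is a free modeling choice, documented rather than fitted, and it is
erased by normalization anyway. A per-patient *diversity* parameter d
interpolates between a patient dominated by one archetype (d ≈ 0) and
plaques drawn iid from the cohort mixture (d = 1); the simulated tau grade
increases with d, which couples advanced-pathology strata to higher
per-patient heterogeneity. Validation scenarios that state their condition
purely at the plaque-mixture level (e.g. "a DS-only archetype at weight
0.3") use d = 1, the direct realization of that condition.

`generate_lambda_stack()` renders plaques as disks with a parabolic radial
falloff over a broad low-level background autofluorescence, with truth
masks; it supports non-overlapping placement for detection benchmarks. It
deliberately does not model plaque morphotypes (cored vs diffuse),
photobleaching kinetics, tau tangles, or vascular amyloid — so passing
segmentation benchmarks demonstrate correctness of the thresholding and
labeling machinery on disk-like, high-SNR objects, not performance on real
tissue.

## Segmentation

Plaques are segmented on the total-intensity projection (the sum over all
channels of all dyes) — which channel or combination the original analysis
thresholded is not stated, so the projection is a documented default.
Otsu's threshold (parameter-free) or a fixed threshold, connected
components at 4- (default, via `EBImage::bwlabel`) or 8-connectivity (a
run-length union-find implemented here), an area band of [50, 50000] px at
512×512 by default, and stable raster-order relabeling. The manual
false-positive exclusion step of the original workflow is reproduced as a
file-drivable operation (`apply_exclusions()`): explicit label lists or
ROI polygons, with a label removed when more than half its area falls
inside an ROI. Analysis is 2-D, on the single optical plane per field.

## Numerical choices and problem sizes

* PCA and projection tolerances are those of LAPACK via `prcomp`; tests
  compare against a covariance eigendecomposition oracle at 1e-8 after
  sign alignment, and the RMSD implementation against direct formula
  evaluation at 1e-12.
* KDE thresholds use the exact N² kernel sum (no grid approximation) in
  the quantile calibration; the mass calibration uses a 128-per-axis mesh
  padded by 4 kernel sds.
* Degenerate inputs: all-zero dye blocks are flagged, not errors;
  single-vector patients and single-patient cohorts yield `NA` RMSD;
  zero-variance references are a KDE error; zero-variance covariates are a
  regression error; empty images segment to empty mask sets.
* Validation problem sizes were chosen as the smallest that make the
  statistical properties sharp: 20-seed replications for recovery and
  ordering properties, 2000 replicates for MANOVA type-I calibration,
  1000-point references for coverage checks, cohorts at the study's
  patient counts (152/34/24) for the cohort-dispersion ordering, and the
  package-default synthetic scale (33 patients, ~25 plaques each) for the
  end-to-end strain-recovery runs.

## Known limitations

* Real emission spectra have correlated, intensity-dependent noise and
  autofluorescence residue; the generator's additive iid noise is a
  simplification.
* Headline numbers of the motivating study (Λ = 0.74, cohort RMSDs
  0.055/0.030/0.023, PC1 = 62%) depend on ~2700 unreleased spectra and are
  used here only as qualitative anchors (orderings, separations); they are
  not reproduced numerically.
* Eigenspaces fitted on different datasets are not aligned (no
  Procrustes); all comparisons live inside one fitted space.
* No spectral unmixing or baseline correction; the assay's photobleaching
  step replaces them upstream.
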