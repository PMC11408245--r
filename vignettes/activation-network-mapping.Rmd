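---
title: "Activation network mapping: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation network mapping: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `anmapr`: the model
behind each stage, the parameters that matter and why their defaults are what
they are, what the synthetic ground-truth generator does and does not
emulate, and the numerical and design decisions taken where conventions
diverge.

## 1. The mapping model

Activation network mapping treats each published experiment's activation
foci not as locations of interest in themselves but as *seeds* into a
normative functional connectome. The model has four stages.

**Seeds.** All foci of one experiment (one task contrast) are dilated into
4 mm-radius spheres and merged into a combined seed. Sphere membership is by
voxel-centre Euclidean distance with an inclusive `<=`; this is deterministic
and independent of grid conventions (a 4 mm sphere on a 2 mm isotropic grid
contains exactly 33 voxels, by lattice enumeration of offsets with
i²+j²+k² ≤ 4). Talairach-space foci are premapped to MNI with the Lancaster
ICBM/SPM-pose affine's inverse; the matrix is stored in code
(`icbm_spm2tal_matrix()`) and the transform is configurable, since coordinate
conversion conventions differ between labs and the choice is rarely reported.
Foci outside the grid produce warnings, not errors; an experiment errors only
if *no* focus lands on the grid.

**Connectivity.** For each subject of the connectome, the seed signal is the
unweighted mean time series over seed voxels — the standard seed-based
convention — and connectivity is the Pearson correlation of that signal with
every brain voxel. Correlations are variance-stabilized with Fisher's
z = atanh(r); |r| = 1 is clipped to 1 − 1e−7 first (logged) so the transform
stays finite. Voxels with zero temporal variance get r = 0 rather than
missing, so downstream overlap arithmetic never sees gaps.

**Experiment-level inference.** Subject z-maps are tested against zero with
a voxelwise one-sample t (df = n − 1), computed streamingly from running
sums so that a 1000-subject connectome never has to fit in memory
(`compute_experiment_tmaps()` accepts a subject-loading function). The map
is binarized at t > 3, *one-sided*: the published description is "thresholded
at t > 3", so negative connectivity is discarded. Voxels with zero
across-subject variance are set to t = 0 and counted.

**Consensus.** The binarized maps are summed into an overlap-count map and
thresholded at a fraction of the number of experiments E. The required count
is `ceil(fraction * E)` — a strict-majority reading: for E = 11 at 60 % this
gives 7 of 11, the count the source analysis reports. Robustness is
quantified with the Dice coefficient 2|A∩B|/(|A|+|B|) under single-parameter
perturbations (overlap fractions {0.5, 0.6, 0.7}, t thresholds
{2.5, 3, 3.5}, seed radii {4, 6, 8, 10} mm — the named alternatives where the
analysis names any, plausible brackets otherwise) and by
leave-one-experiment-out. The Dice of two empty masks is defined as 1
(logged) so degenerate sweep cells do not abort a run.

## 2. Specificity

Disease-specificity contrasts run the identical pipeline on a control
cohort's coordinate table (a shared configuration object enforces identical
parameters) and compare group mean z-maps inside anatomically defined ROIs.
t-maps are converted to z-maps probability-preservingly,
z = Φ⁻¹(F_t(t; df)), evaluated through log tail probabilities symmetrically
per tail so |t| of 30+ maps to finite z rather than saturating. The contrast
statistic is Cohen's d over the two maps' ROI voxel-value distributions with
the pooled-SD (n₁+n₂−2) variant; the voxelwise-distribution reading (rather
than subject-level summaries) is adopted because the compared objects are
group mean maps. No p-value is attached to d, deliberately: ROI voxels are
spatially dependent, so a naive test would be anticonservative.

## 3. Transcriptomic decoding

The consensus map is downsampled to atlas regions (mean over region voxels;
missing regions are flagged NA and excluded), restricted to one hemisphere
by default (donor coverage of expression atlases is left-dominant), and
related to a region × gene expression matrix.

*Gene filtering.* Genes are kept when their mean inter-donor correlation of
regional profiles ("differential stability") is strictly above 0.1, then
averaged across donors. The strict inequality matches the "above 0.1"
phrasing and is tested at the boundary.

*PLS1.* With a univariate response, the first PLS component's weight vector
is exactly proportional to Xᵀy after column standardization; `pls1_fit()`
implements that closed form (normalized to unit length) and reports
explained variance as cor(scores, y)². Both X columns and y are z-scored —
the scale-free choice, and the one that makes the closed form exact.

*Spatial significance.* Whether PLS1 explains more variance than chance is
tested against Moran spectral randomization surrogates: y is decomposed on
the orthonormal eigenbasis of the doubly centred spatial weight matrix
(row-standardized inverse centroid distance, symmetrized; a k-nearest-
neighbour option is provided), coefficients are sign-flipped at random
(the singleton procedure — this preserves the squared-coefficient profile
and hence Moran's I exactly), and each surrogate is then re-centred and
re-scaled to y's exact mean and variance. The explicit moment enforcement
matters numerically: within degenerate eigenspaces the basis need not
separate the constant vector exactly, and the contract is exact moment
preservation. p = (1 + #{surrogate ≥ observed})/(1 + n); ties count against
the observation.

*Gene scoring.* Each gene's z is its weight divided by its bootstrap SE over
region resamples (components sign-aligned to the response). The ratio is
computed on the **per-gene correlation scale**, not the unit-norm weight
scale: the global norm couples all genes — under a pure-noise model the
resampled norm is inflated by ≈ √2 (the bootstrap adds one sampling-noise
variance on top of each observed coefficient), which would deflate every
bootstrap SD and inflate every z by the same factor; we measured sd(z) ≈ 1.47
on an iid null with the norm in place and ≈ 1.05 without it. Selection at
|z| > 3.69 (two-sided normal tail ≈ 2×10⁻⁴) with BH q-values reported.

*Enrichment.* A local hypergeometric over-representation test (upper tail,
BH-corrected across terms) against a user-supplied annotation list and
background; web meta-enrichment services are out of scope.

## 4. Neurotransmitter decoding

Receptor/transporter tracer images are combined participant-weighted within
receptor (Σnᵢmᵢ/Σnᵢ), averaged unweighted within neurotransmitter system,
parcellated, and z-scored across regions. The consensus map's regional
values are regressed on the five system maps by OLS with intercept, and R²
is decomposed into per-system shares by the LMG metric: the average over all
orderings of the incremental R² when the predictor enters. With five
predictors this is computed exactly via the subset-weighting identity
(32 subset R² values; equivalent to enumerating all 120 orderings, which the
test suite does as an independent oracle). LMG is the default metric of the
established relative-importance methodology for collinear regressors; shares
are non-negative and sum to the unadjusted R². Confidence intervals are
percentile bootstrap over region resamples; predictor significance is the
OLS t-test p-value BH-corrected across the five systems.

## 5. Term decoding

A generic stand-in for database-driven cognitive decoding: each term map is
scored by its mean value inside the consensus mask, compared against a
permutation null that relocates the mask's voxel labels uniformly within the
brain (seeded, configurable count), with BH control across terms. The mean
in-mask value is used rather than a correlation because the decoding mask is
binary; the scoring statistic of the external service this emulates is not
publicly specified, so the choice is documented and configurable.

## 6. The synthetic generator: what it emulates, and what it does not

`synthetic_scenario()` plants ground truth for every stage:

- **Connectome** — per subject, a standard-normal latent series drives every
  voxel of a spherical "true network" with amplitude `snr` on top of unit
  white noise; other voxels are pure noise. In-network voxel pairs then
  correlate at snr²/(snr²+1) (0.5 at the default snr = 1). Default study
  scale: 20³ voxels of 2 mm, 50 subjects × 150 timepoints, E = 11
  experiments × 3 foci — chosen as the largest configuration that keeps the
  full test suite in minutes.
- **Atlas** — contiguous box regions tiling the grid, half per hemisphere
  (40 by default; 246 with a 123-region left hemisphere for the
  transcriptomic experiments).
- **Expression** — signal genes are `gene_effect`·standardized(target) plus
  complementary smooth noise; noise genes are smooth noise; donors add
  independent noise calibrated so stable genes clear the 0.1 similarity
  filter (similarity ≈ 1/(1+sd²) ≈ 0.5 at the default donor noise) while a
  configurable fraction of donor-inconsistent genes falls below it.
- **Receptors** — five system profiles constructed so that the planted
  linear combination (+0.33 noradrenaline, −0.24 GABA by default) plus
  smooth noise reproduces the target at a configured R² (0.2 by default);
  one receptor is split into two tracer cohorts whose weighted average
  reconstructs the underlying map exactly, exercising the weighted-averaging
  path.

The regional noise fields are Gaussian-kernel smoothed over centroids with a
4 mm length scale — mild autocorrelation, deliberately below the toy atlas's
~10 mm centroid spacing, consistent with parcel averaging having removed
voxel-scale smoothness. Targets in the *spatial-null* experiments are
smoothed at 12 mm so the MSR test faces genuinely autocorrelated maps.

The generator does **not** emulate hemodynamics, motion, preprocessing
artifacts, empirical connectome covariance structure, microarray probe-level
noise, or tracer kinetics. Passing tests therefore demonstrate the
correctness and calibration of the *statistical machinery* under known
ground truth — not performance on real acquisitions.

## 7. Validation design and calibration caveats

Validation separates two inferential mechanisms that real data confound:

- The **bootstrap gene-selection** experiments (planted-gene recovery; null
  false-selection rate) use a spatially *unstructured* target. Under these
  exchangeable conditions the correlation-scale bootstrap z is calibrated
  (measured null false-selection ≈ 5×10⁻⁴ at |z| > 3.69 on ~1800 genes).
- The **MSR** experiments use strongly autocorrelated null targets against
  spatially *unstructured* control predictors. In that regime the surrogate
  family is exchangeable by rotation invariance, and the measured rejection
  at p ≤ 0.05 is 3–6 % across predictor-set draws (nominal 5 %).

Two caveats worth stating plainly. First, a y-surrogate test that conditions
only on the response's spatial spectrum is *not* exactly calibrated when the
predictors are themselves spatially structured: with strongly smooth null
responses and even mildly smooth gene sets we measured rejection of roughly
10–17 % at nominal 5 %, conditional on the gene-set realization. The effect
worsens, not improves, under richer randomizations we evaluated
(within-block coefficient permutation) and under k-nearest-neighbour
weights (25–50 %), which is why the default stays inverse-distance weights
with sign-flip randomization — the most conservative family tested. On real
data, where expression maps are strongly autocorrelated, MSR p-values should
be read as approximate, with the residual anticonservativeness in mind.

Second, when the response map is a sparse blob and gene maps are smooth,
per-gene bootstrap z-scores are anticonservative — region resampling cannot
see spatial dependence, and false selections become overdispersed across
realizations (we measured per-dataset tail-count ranges of 0–11 per ~1800
null genes across seeds). Gene-level selections on real, strongly
autocorrelated maps are therefore best read as a ranking device rather than
a calibrated family of tests.

Two further desk-scale artifacts are handled explicitly. First, a seed's own
voxels trivially correlate with the seed-mean series, so the pure-noise
suprathreshold rate is measured outside the seed (on a real 900k-voxel grid
the seed's ~33 voxels are negligible; at 20³ they alone would contribute
0.4 %). Second, at very small region counts (≤ 16) the donor-similarity
filter is only statistically sharp: a stray inconsistent gene can clear the
0.1 threshold by chance, so tests bound the leak fraction rather than
demanding zero.

## 8. Numerical conventions

- Consensus count threshold: `ceil(fraction·E − 1e−9)` — the epsilon guards
  against floating-point excess in exact multiples (0.6 × 10 must require 6,
  not 7).
- `t_to_z` uses log-CDF evaluation per tail; p-value preservation is tested
  to 1e−10 over t ∈ [−8, 8], df ∈ {2, 10, 999}.
- PLS with constant response or all-orthogonal predictors errors; constant
  predictor columns are z-scored to zero (no signal) rather than NaN.
- Bootstrap resamples with constant response are redrawn (counted); genes
  with zero bootstrap SD are flagged (`n_degenerate`) and given signed
  infinite z (zero weight → z = 0).
- All stochastic stages take explicit integer seeds; scenario substreams are
  fanned out deterministically from the master seed, and generators are
  bit-reproducible per (seed, index).

## 9. Problem sizes

The shipped validation runs use: 50 subjects × 150 timepoints on 20³ grids
for network recovery; 100 subjects for the noise-floor measurement; a
246-region atlas with 123-region hemisphere, ~2000 genes, 500 bootstrap
resamples, and 99 surrogates × 200 replicates for the decoding calibrations;
40 replicates for receptor recovery. These sizes were chosen so the whole
suite completes in a few minutes while every assertion retains comfortable
statistical margin; the same code paths scale to full-size inputs (the
connectome loop is O(subjects) in time and O(1) in subjects held in memory).

## 10. Known limitations

- Surface-based (vertex) seeds are out of scope; everything is volumetric.
- The disease-control specificity contrast reports effect size only.
- MSR's weight matrix is a modelling choice (inverse distance default, kNN
  option); the surrogate family conditions on it.
- The packaged experiment table's focus coordinates are synthetic stand-ins
  (its study structure and group sizes are real); analyses of the real
  networks require the original supplementary coordinates.
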