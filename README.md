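# anmapr

Coordinate-based **activation network mapping** (ANM) for task-fMRI
meta-analysis, with transcriptomic and neurotransmitter decoding of the
resulting network.

## The problem

Task-fMRI studies contrasting clinical groups (for instance depressive
patients with versus without a history of suicide attempts) report activation
differences at scattered, poorly reproducible coordinates. ANM asks a
different question: do these heterogeneous foci, whatever their location,
connect to one *common brain network*? Each experiment's reported foci are
turned into a combined spherical seed, each seed's resting-state functional
connectivity map is estimated in a large normative connectome, the resulting
experiment-level statistical maps are thresholded, and the voxels reached by
a majority of experiments form the consensus network. That network can then
be decoded against regional gene expression, receptor density maps, and
meta-analytic term maps.

`anmapr` is aimed at neuroimaging researchers running coordinate-based
network mapping who want a tested, scriptable pipeline plus a synthetic
ground-truth generator to validate every stage without any data downloads.

## Method summary

For experiment *e* with foci *x₁…x_k* (MNI mm; Talairach foci are converted
with the Lancaster tal2icbm affine):

1. **Seeds** — combined seed S_e = union of 4 mm-radius spheres at each focus.
2. **Connectivity** — for each connectome subject, r = Pearson correlation of
   the seed-mean time series with every brain voxel; z = atanh(r); the
   experiment-level map is the voxelwise one-sample t statistic of the
   subject z-maps against 0 (df = n − 1).
3. **Consensus** — binarize at t > 3 (positive tail) and keep voxels present
   in ≥ ceil(0.6 E) of the E experiments. Robustness: Dice overlap of the
   consensus under perturbed thresholds/seed radii and leave-one-experiment-out.
4. **Specificity** — convert t to z by Φ⁻¹(F_t(t; df)), average within groups,
   compare z distributions inside a-priori ROIs with Cohen's d (pooled SD).
5. **Transcriptomics** — regional consensus values y (per-hemisphere) against
   a region × gene matrix X (donor-averaged, genes filtered at inter-donor
   similarity > 0.1): PLS1 weights w ∝ Xᵀy; significance of explained
   variance by Moran spectral randomization (spatially constrained
   surrogates of y); per-gene z = weight / bootstrap SE with selection at
   |z| > 3.69; local hypergeometric over-representation for gene sets.
6. **Receptors** — Ov = β₀ + β₁·Dopamine + β₂·GABA + β₃·Glutamate +
   β₄·Noradrenaline + β₅·Serotonin + ε over atlas regions (tracer images
   participant-weighted per receptor, averaged per system, z-scored), with
   an exact LMG relative-importance decomposition of R² and bootstrap CIs.

## Worked example

Everything below runs in seconds on a laptop; the synthetic scenario plants
a known spherical network into a simulated connectome.

```r
library(anmapr)

sc      <- synthetic_scenario(dim = 16L, n_subjects = 20L, n_timepoints = 100L,
                              n_experiments = 6L, n_regions = 16L,
                              network_radius = 8, rng_seed = 1L)
grid    <- scenario_grid(sc)
records <- as_experiment_records(simulate_coordinate_table(sc, grid))
seeds   <- lapply(records, combine_experiment_seed, radius = 4, grid = grid)
tmaps   <- compute_experiment_tmaps(subject_generator(sc, grid), seeds,
                                    n_subjects = sc$n_subjects)
binmaps   <- lapply(tmaps, threshold_binarize, t_thresh = 3)
consensus <- consensus_mask(overlap_counts(binmaps), fraction = 0.6)
consensus
#> <brain_mask> 294 / 4096 voxels set
dice(consensus, planted_network(sc, grid))
#> [1] 0.9760956
head(leave_one_experiment_out(binmaps, 0.6), 3)
#>      left_out_id      dice
#> 1 study01|task01 0.9983022
#> 2 study02|task02 0.9983022
#> 3 study03|task03 0.9983022
```

The consensus mask recovers the planted network almost exactly (Dice 0.98)
and is stable when any single experiment is dropped (Dice ≥ 0.997).

Decoding a parcellated network against synthetic receptor systems planted
with weights +0.33 (noradrenaline) and −0.24 (GABA):

```r
sc      <- synthetic_scenario(n_regions = 246L, rng_seed = 1L)
grid    <- scenario_grid(sc)
atlas   <- make_toy_atlas(sc, grid)
ov      <- parcellate_map(planted_network(sc, grid), atlas)
systems <- build_system_maps(simulate_receptor_maps(sc, ov, atlas), atlas)
fit_receptor_model(ov, systems)
#> <receptor_fit> adj R2 = 0.293, F(5,240) = 21.27, p = 1.34e-17
#>   (Intercept)      dopamine          GABA     glutamate noradrenaline
#>        0.0457        0.0016       -0.0763       -0.0108        0.0998
#>     serotonin
#>       -0.0124
bootstrap_relative_importance(ov, systems, n_boot = 1000, rng_seed = 2)
#>          system     beta     q pct_of_r2 ci_lo ci_hi
#> 1      dopamine  0.00159 0.858     0.286 0.000 0.009
#> 2          GABA -0.07634 0.000    29.387 0.053 0.135
#> 3     glutamate -0.01078 0.261     1.343 0.000 0.021
#> 4 noradrenaline  0.09983 0.000    68.139 0.109 0.304
#> 5      serotonin -0.01237 0.259     0.844 0.000 0.015
```

The two planted systems are the two FDR-significant ones, with the correct
signs and noradrenaline taking the dominant share of the model R².

A full on-disk run (NIfTI volumes, TSV tables, JSON sidecars) goes through
`write_scenario_inputs()` + `run_all()`, or the thin CLI:

```sh
exec/anm simulate --scenario scenario.yaml --out inputs/
exec/anm run      --config run.yaml        --out outputs/
```

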