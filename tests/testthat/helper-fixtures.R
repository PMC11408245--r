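# Shared tiny fixtures built in code.

tiny_grid <- function(n = 10L, vs = 2) default_grid(n, vs)

# A deterministic subject whose data we control column-by-column.
manual_subject <- function(data, grid = tiny_grid(), mask = NULL) {
  if (is.null(mask)) mask <- brain_mask(grid, array(TRUE, grid$shape))
  subject_time_series(data, grid, mask, subject_id = "manual")
}

# Mask from linear voxel indices.
mask_from_idx <- function(idx, grid = tiny_grid()) {
  v <- array(FALSE, grid$shape)
  v[idx] <- TRUE
  brain_mask(grid, v)
}

# Brute-force sphere membership by lattice enumeration (independent oracle).
brute_sphere_count <- function(center, radius, grid) {
  ctr <- voxel_centers(grid)
  sum(sqrt(rowSums(sweep(ctr, 2, center)^2)) <= radius + 1e-9)
}

# Tiny desk scenario used by several module tests; `...` overrides defaults.
tiny_scenario <- function(...) {
  defaults <- list(dim = 14L, n_subjects = 10L, n_timepoints = 80L,
                   n_experiments = 4L, foci_per_experiment = 3L,
                   n_regions = 8L, n_genes = 60L, n_signal_genes = 6L,
                   network_radius = 7, rng_seed = 7L)
  do.call(synthetic_scenario, utils::modifyList(defaults, list(...)))
}
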