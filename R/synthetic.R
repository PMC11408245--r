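#' Synthetic study scenario
#'
#' Bundles every parameter of the synthetic ground-truth generators: a small
#' isotropic grid with a planted, spatially contiguous "true network", a
#' normative-connectome emulation whose in-network voxels share a latent
#' signal, a coordinate table sampled inside the network, a toy parcellation
#' atlas with an L/R split, spatially autocorrelated gene maps with a planted
#' signal subset, and receptor maps built as a known linear combination of a
#' target map.
#'
#' Defaults are desk-scale: a 20^3 voxel 2 mm grid, 50 subjects with 150
#' timepoints, 11 experiments of 3 foci, SNR 1 (in-network voxel pairs then
#' correlate at snr^2/(snr^2+1) = 0.5), a 40-region atlas, 500 genes of which
#' 30 carry signal at correlation 0.6.
#'
#' @param dim Grid voxels per axis (length 1 or 3).
#' @param voxel_size Voxel edge, mm.
#' @param n_subjects,n_timepoints Connectome emulation size.
#' @param n_experiments,foci_per_experiment Coordinate table shape.
#' @param snr Latent-signal amplitude for in-network voxels (noise SD 1).
#' @param network_radius Radius (mm) of the planted spherical network.
#' @param network_center World-mm centre of the planted network.
#' @param n_regions Atlas regions (even, half per hemisphere).
#' @param n_genes,n_signal_genes,gene_effect Expression emulation: total
#'   genes, planted signal genes, and their correlation with the target map.
#' @param n_donors Donor copies of the expression matrix.
#' @param donor_noise_sd Per-donor noise SD for stable genes (inter-donor
#'   similarity 1/(1+sd^2)).
#' @param unstable_fraction Fraction of noise genes made donor-inconsistent
#'   (dropped by the 0.1 similarity filter).
#' @param receptor_weights Named length-5 vector of planted system weights.
#' @param receptor_r2 Target R^2 of the planted receptor model.
#' @param smooth_scale Gaussian length scale (mm) of the spatially
#'   autocorrelated regional noise. The default (4 mm, below the toy atlas's
#'   roughly 10 mm centroid spacing) gives mild parcel-level autocorrelation,
#'   as parcel averaging leaves little of the voxel-scale smoothness.
#' @param decoy_fraction Fraction of foci drawn outside the planted network.
#' @param rng_seed Integer master seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(dim = c(20L, 20L, 20L), voxel_size = 2,
                               n_subjects = 50L, n_timepoints = 150L,
                               n_experiments = 11L, foci_per_experiment = 3L,
                               snr = 1, network_radius = 9,
                               network_center = c(0, 0, 0),
                               n_regions = 40L,
                               n_genes = 500L, n_signal_genes = 30L,
                               gene_effect = 0.6, n_donors = 6L,
                               donor_noise_sd = 1, unstable_fraction = 0.1,
                               receptor_weights = c(dopamine = 0, GABA = -0.24,
                                                    glutamate = 0,
                                                    noradrenaline = 0.33,
                                                    serotonin = 0),
                               receptor_r2 = 0.2, smooth_scale = 4,
                               decoy_fraction = 0, rng_seed = 42L) {
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  stopifnot(snr > 0, n_signal_genes <= n_genes, n_regions >= 4L,
            n_regions %% 2L == 0L, gene_effect >= 0, gene_effect <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  stopifnot(setequal(names(receptor_weights), NEUROTRANSMITTER_SYSTEMS))
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario> %dx%dx%d @ %g mm, %d subjects x %d TRs, ",
                     "E = %d, R = %d regions, %d genes (seed %d)\n"),
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size, x$n_subjects,
              x$n_timepoints, x$n_experiments, x$n_regions, x$n_genes,
              x$rng_seed))
  invisible(x)
}

#' Grid of a synthetic scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @return The scenario's [volume_grid()] (isotropic, origin-centred).
#' @export
scenario_grid <- function(scenario) {
  default_grid(scenario$dim, scenario$voxel_size, space_label = "synthetic")
}

# per-purpose deterministic substream seeds fanned out from the master seed
.sub_seed <- function(scenario, offset) {
  as.integer((scenario$rng_seed * 1009L + offset) %% 2147483647L)
}

#' Planted ground-truth network mask
#'
#' A spherical, spatially contiguous network of voxels around the scenario's
#' network centre.
#'
#' @param scenario A [synthetic_scenario()].
#' @param grid Optional pre-built grid (defaults to the scenario grid).
#' @return A non-empty [brain_mask()].
#' @export
planted_network <- function(scenario, grid = scenario_grid(scenario)) {
  m <- build_sphere_mask(scenario$network_center, scenario$network_radius, grid)
  if (!any(m$voxels)) stop("planted network is empty: enlarge the grid or radius")
  m
}

#' Toy parcellation atlas
#'
#' Tiles the grid with contiguous box-shaped regions: the left half of the x
#' axis holds R/2 regions tagged L, the right half R/2 tagged R. Boxes are
#' near-equal volume; centroids are mean voxel world coordinates.
#'
#' @inheritParams planted_network
#' @return A [region_atlas()].
#' @export
make_toy_atlas <- function(scenario, grid = scenario_grid(scenario)) {
  R2 <- scenario$n_regions %/% 2L
  nx <- grid$shape[1]
  if (nx < 2L || prod(grid$shape) < scenario$n_regions)
    stop("grid too small for ", scenario$n_regions, " regions")
  half <- nx %/% 2L
  labels <- array(0L, grid$shape)
  labels[seq_len(half), , ] <- .tile_boxes(c(half, grid$shape[2], grid$shape[3]), R2)
  rest <- nx - half
  labels[(half + 1):nx, , ] <-
    .tile_boxes(c(rest, grid$shape[2], grid$shape[3]), R2) + R2
  region_atlas(grid, labels,
               hemisphere = rep(c("L", "R"), each = R2),
               name = sprintf("toy%d", scenario$n_regions))
}

# split a box into n contiguous near-equal boxes (z slabs -> y strips -> x)
.tile_boxes <- function(shape, n) {
  if (n > prod(shape)) stop("grid too small to tile ", n, " regions")
  lab <- array(0L, shape)
  kz <- max(1L, min(shape[3], round(n^(1 / 3))))
  z_cuts <- .split_axis(shape[3], kz)
  z_counts <- .split_counts(n, kz)
  nxt <- 0L
  for (zi in seq_len(kz)) {
    nz <- z_counts[zi]
    if (nz == 0L) next
    ky <- max(1L, min(shape[2], round(sqrt(nz))))
    y_cuts <- .split_axis(shape[2], ky)
    y_counts <- .split_counts(nz, ky)
    for (yi in seq_len(ky)) {
      nyc <- y_counts[yi]
      if (nyc == 0L) next
      x_cuts <- .split_axis(shape[1], min(nyc, shape[1]))
      if (length(x_cuts) < nyc) stop("grid too small to tile ", n, " regions")
      for (xi in seq_len(nyc)) {
        lab[x_cuts[[xi]], y_cuts[[yi]], z_cuts[[zi]]] <- nxt + xi
      }
      nxt <- nxt + nyc
    }
  }
  lab
}

.split_axis <- function(len, k) {
  bounds <- round(seq(0, len, length.out = k + 1))
  lapply(seq_len(k), function(i) (bounds[i] + 1):bounds[i + 1])
}

.split_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' One synthetic connectome subject
#'
#' Subject i's series: a standard-normal latent series drives every voxel of
#' the planted network with amplitude `snr` on top of unit white noise;
#' voxels outside the network are pure unit noise. Deterministic per
#' (scenario seed, subject index).
#'
#' @inheritParams planted_network
#' @param i Subject index.
#' @return A [subject_time_series()] with a whole-grid brain mask.
#' @export
simulate_subject <- function(scenario, i, grid = scenario_grid(scenario)) {
  net <- planted_network(scenario, grid)
  mask <- brain_mask(grid, array(TRUE, grid$shape))
  set.seed(.sub_seed(scenario, 100000L + i))
  T <- scenario$n_timepoints
  V <- n_voxels(grid)
  latent <- stats::rnorm(T)
  data <- matrix(stats::rnorm(T * V), T, V)
  innet <- which(net$voxels)
  data[, innet] <- data[, innet] + scenario$snr * latent
  subject_time_series(data, grid, mask, subject_id = sprintf("sub%04d", i))
}

#' Generator function over synthetic subjects
#'
#' @inheritParams planted_network
#' @return A function `f(i)` returning [simulate_subject()] output, suitable
#'   for [compute_experiment_tmaps()] streaming.
#' @export
subject_generator <- function(scenario, grid = scenario_grid(scenario)) {
  force(scenario); force(grid)
  function(i) simulate_subject(scenario, i, grid)
}

#' Materialized list of synthetic subjects
#'
#' Convenience wrapper materializing all subjects; prefer
#' [subject_generator()] for large scenarios.
#'
#' @inheritParams planted_network
#' @return List of [subject_time_series()].
#' @export
simulate_connectome <- function(scenario, grid = scenario_grid(scenario)) {
  lapply(seq_len(scenario$n_subjects), simulate_subject,
         scenario = scenario, grid = grid)
}

#' Synthetic coordinate table
#'
#' Draws each experiment's foci uniformly from the planted network's voxel
#' centres (with an optional decoy fraction drawn from outside), one study
#' per experiment, with plausible group sizes.
#'
#' @inheritParams planted_network
#' @return A coordinate-table data frame (see [read_coordinate_table()]).
#' @export
simulate_coordinate_table <- function(scenario, grid = scenario_grid(scenario)) {
  net <- planted_network(scenario, grid)
  ctr <- voxel_centers(grid)
  inside <- which(net$voxels)
  outside <- which(!net$voxels)
  set.seed(.sub_seed(scenario, 200000L))
  rows <- list()
  for (e in seq_len(scenario$n_experiments)) {
    k <- scenario$foci_per_experiment
    n_out <- round(scenario$decoy_fraction * k)
    pick <- c(sample(inside, k - n_out, replace = length(inside) < k),
              if (n_out > 0) sample(outside, n_out))
    rows[[e]] <- data.frame(
      study_id = sprintf("study%02d", e),
      task_label = sprintf("task%02d", e),
      space = "MNI",
      x = ctr[pick, 1], y = ctr[pick, 2], z = ctr[pick, 3],
      n_case = sample(10:40, 1), n_control = sample(10:40, 1),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# smooth, z-scored regional noise fields: Gaussian kernel over centroids
.smooth_region_noise <- function(centroids, n_fields, length_scale) {
  d2 <- as.matrix(stats::dist(centroids))^2
  K <- exp(-d2 / (2 * length_scale^2))
  K <- K / rowSums(K)
  raw <- matrix(stats::rnorm(nrow(centroids) * n_fields), nrow(centroids), n_fields)
  sm <- K %*% raw
  apply(sm, 2, function(v) as.numeric(scale(v)))
}

#' Synthetic per-donor expression matrices
#'
#' Signal genes follow `gene_effect * standardized(target) +
#' sqrt(1 - gene_effect^2) * smooth noise`; noise genes are smooth spatial
#' noise alone. Donor copies add independent donor noise: stable genes get
#' noise at `donor_noise_sd` (inter-donor similarity about
#' 1/(1+sd^2), above the 0.1 filter at the default), while an
#' `unstable_fraction` of the noise genes is redrawn independently per donor
#' and so falls below the filter.
#'
#' @inheritParams planted_network
#' @param target A [region_vector()] the signal genes covary with (e.g. the
#'   parcellated consensus map).
#' @param atlas The [region_atlas()] providing centroids for `target`'s
#'   regions.
#' @return List of `n_donors` [expression_matrix()] objects; the planted
#'   signal genes are named `sig0001..` and carried in the
#'   `signal_genes` attribute.
#' @export
simulate_expression <- function(scenario, target, atlas) {
  stopifnot(inherits(target, "region_vector"))
  ctr <- atlas$centroids[target$regions, , drop = FALSE]
  R <- length(target$values)
  G <- scenario$n_genes
  ns <- scenario$n_signal_genes
  tz <- as.numeric(scale(target$values))
  if (!all(is.finite(tz))) stop("constant target map")
  set.seed(.sub_seed(scenario, 300000L))
  base <- .smooth_region_noise(ctr, G, scenario$smooth_scale)
  if (ns > 0) {
    a <- scenario$gene_effect
    base[, seq_len(ns)] <- a * tz + sqrt(1 - a^2) * base[, seq_len(ns), drop = FALSE]
  }
  genes <- c(sprintf("sig%04d", seq_len(ns)),
             sprintf("noise%04d", seq_len(G - ns)))
  n_unstable <- round(scenario$unstable_fraction * (G - ns))
  unstable <- if (n_unstable > 0) ns + seq_len(n_unstable) else integer(0)
  donors <- lapply(seq_len(scenario$n_donors), function(d) {
    set.seed(.sub_seed(scenario, 310000L + d))
    vals <- base + scenario$donor_noise_sd * matrix(stats::rnorm(R * G), R, G)
    if (length(unstable))
      vals[, unstable] <- .smooth_region_noise(ctr, length(unstable),
                                               scenario$smooth_scale)
    expression_matrix(vals, target$regions, genes, donor_id = sprintf("donor%d", d))
  })
  attr(donors, "signal_genes") <- genes[seq_len(ns)]
  attr(donors, "unstable_genes") <- genes[unstable]
  donors
}

#' Synthetic receptor/transporter tracer maps
#'
#' Builds five system-level regional profiles such that
#' `sum(weights * systems)` plus smooth spatial noise reproduces the target
#' map at roughly the configured R^2 (`receptor_r2 = 1` means noiseless).
#' Systems with zero planted weight are independent smooth fields; the
#' nonzero-weight systems absorb the target. Profiles are volumized onto the
#' atlas and emitted as tracer images; the dopamine system's D2 receptor is
#' split into two tracer images with distinct cohort sizes whose
#' participant-weighted average equals the underlying map exactly, and the
#' serotonin system carries two single-tracer receptors.
#'
#' @inheritParams simulate_expression
#' @return List of [tracer_map()]s; the planted system regional profiles are
#'   attached as the `system_profiles` attribute (named list of
#'   [region_vector()]s).
#' @export
simulate_receptor_maps <- function(scenario, target, atlas) {
  stopifnot(inherits(target, "region_vector"))
  w <- scenario$receptor_weights[NEUROTRANSMITTER_SYSTEMS]
  ctr <- atlas$centroids[target$regions, , drop = FALSE]
  R <- length(target$values)
  set.seed(.sub_seed(scenario, 400000L))
  free <- .smooth_region_noise(ctr, 5L, scenario$smooth_scale)
  colnames(free) <- NEUROTRANSMITTER_SYSTEMS
  nz <- names(w)[w != 0]
  profiles <- free
  if (length(nz)) {
    r2 <- scenario$receptor_r2
    noise_sd <- if (r2 >= 1) 0 else stats::sd(target$values) * sqrt((1 - r2) / r2)
    noise <- if (noise_sd > 0)
      noise_sd * .smooth_region_noise(ctr, 1L, scenario$smooth_scale) else 0
    clean <- target$values - noise
    # the last nonzero-weight system absorbs the residual so that
    # sum_i w_i * profile_i == clean holds exactly
    carrier <- nz[length(nz)]
    others <- setdiff(nz, carrier)
    acc <- clean
    for (s in others) acc <- acc - w[s] * profiles[, s]
    profiles[, carrier] <- acc / w[carrier]
  }
  maps <- list()
  add <- function(vals, receptor, system, n) {
    maps[[length(maps) + 1L]] <<- tracer_map(vals, atlas$grid, receptor, system, n)
  }
  vol <- function(s) volumize_region_vector(
    region_vector(profiles[, s], target$regions, name = s), atlas)
  # dopamine: D1 single tracer; D2 split into two cohorts that average back
  d2 <- vol("dopamine")
  delta <- 0.5 * stats::sd(profiles[, "dopamine"])
  add(d2 + delta, "D2", "dopamine", 10)
  add(d2 - delta * (10 / 30), "D2", "dopamine", 30)
  add(vol("dopamine"), "D1", "dopamine", 25)
  add(vol("GABA"), "GABA_A", "GABA", 16)
  add(vol("glutamate"), "mGluR5", "glutamate", 28)
  add(vol("noradrenaline"), "NAT", "noradrenaline", 77)
  add(vol("serotonin"), "5-HT1a", "serotonin", 35)
  add(vol("serotonin"), "5-HTT", "serotonin", 100)
  attr(maps, "system_profiles") <- lapply(
    stats::setNames(nm = NEUROTRANSMITTER_SYSTEMS),
    function(s) region_vector(profiles[, s], target$regions, name = s,
                              atlas_name = atlas$name))
  maps
}

#' Group tracer maps into z-normalized system maps
#'
#' Applies [weighted_tracer_average()] within each receptor that has several
#' tracer images, then [system_map()] within each system.
#'
#' @param maps List of [tracer_map()]s.
#' @param atlas A [region_atlas()].
#' @return Named list of five z-normalized system [region_vector()]s.
#' @export
build_system_maps <- function(maps, atlas) {
  systems <- unique(vapply(maps, function(m) m$system, character(1)))
  out <- lapply(stats::setNames(nm = systems), function(s) {
    ms <- Filter(function(m) m$system == s, maps)
    recs <- unique(vapply(ms, function(m) m$receptor, character(1)))
    per_receptor <- lapply(recs, function(r)
      weighted_tracer_average(Filter(function(m) m$receptor == r, ms)))
    system_map(per_receptor, atlas)
  })
  out[intersect(NEUROTRANSMITTER_SYSTEMS, names(out))]
}
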