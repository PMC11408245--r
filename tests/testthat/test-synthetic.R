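test_that("the toy atlas tiles the grid with contiguous equal-ish boxes split L/R", {
  sc <- tiny_scenario(n_regions = 8L)
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  expect_equal(atlas$n_regions, 8L)
  expect_equal(sort(unique(as.integer(atlas$labels))), 1:8)  # full coverage, no background
  expect_equal(sum(atlas$labels == 0L), 0L)
  # label histogram equals region volumes
  hist <- tabulate(as.integer(atlas$labels), 8L)
  ctr <- voxel_centers(g)
  for (r in c(1L, 5L)) {
    expect_equal(hist[r], sum(atlas$labels == r))
    expect_equal(atlas$centroids[r, ],
                 colMeans(ctr[as.integer(atlas$labels) == r, ]))
  }
  expect_equal(atlas$hemisphere, rep(c("L", "R"), each = 4))
  # left-half regions sit at negative x
  expect_true(all(atlas$centroids[1:4, 1] < 0))
  # y/z centroids of a full-depth region are centred on the world origin
  sc4 <- tiny_scenario(n_regions = 4L)
  atlas4 <- make_toy_atlas(sc4, scenario_grid(sc4))
  expect_equal(max(abs(atlas4$centroids[, 2:3])), 0, tolerance = 1e-12)
  expect_error(make_toy_atlas(synthetic_scenario(dim = 4L, n_regions = 200L)),
               "too small")
})

test_that("synthetic subjects are reproducible and carry the planted correlation", {
  sc <- synthetic_scenario(dim = 10L, n_timepoints = 200L, network_radius = 6,
                           rng_seed = 5L)
  s1 <- simulate_subject(sc, 3)
  s2 <- simulate_subject(sc, 3)
  expect_identical(s1$data, s2$data)          # same seed, same subject: bit-identical
  expect_false(isTRUE(all.equal(s1$data, simulate_subject(sc, 4)$data)))
  # expected in-network pairwise correlation at snr 1 is snr^2/(snr^2+1) = 0.5
  g <- scenario_grid(sc)
  net_idx <- which(planted_network(sc, g)$voxels)
  rbar <- mean(vapply(1:30, function(i) {
    d <- simulate_subject(sc, i)$data
    cor(d[, net_idx[1]], d[, net_idx[10]])
  }, numeric(1)))
  expect_equal(rbar, 0.5, tolerance = 0.05)
  # out-of-network voxels stay near zero correlation with the network
  out_idx <- which(!planted_network(sc, g)$voxels)
  rout <- mean(vapply(1:30, function(i) {
    d <- simulate_subject(sc, i)$data
    cor(d[, net_idx[1]], d[, out_idx[5]])
  }, numeric(1)))
  expect_lt(abs(rout), 0.1)
})

test_that("synthetic coordinate tables respect the decoy fraction and row counts", {
  sc <- synthetic_scenario(dim = 14L, n_experiments = 11L,
                           foci_per_experiment = 3L, network_radius = 7)
  df <- simulate_coordinate_table(sc)
  expect_equal(nrow(df), 33L)
  expect_equal(length(unique(paste(df$study_id, df$task_label))), 11L)
  g <- scenario_grid(sc)
  net <- planted_network(sc, g)
  inside <- vapply(seq_len(nrow(df)), function(i) {
    v <- round(world_to_voxel(g, c(df$x[i], df$y[i], df$z[i]))) + 1L
    net$voxels[v[1], v[2], v[3]]
  }, logical(1))
  expect_true(all(inside))
  df_out <- simulate_coordinate_table(synthetic_scenario(dim = 14L,
                                                         decoy_fraction = 1,
                                                         network_radius = 7))
  inside_out <- vapply(seq_len(nrow(df_out)), function(i) {
    v <- round(world_to_voxel(g, c(df_out$x[i], df_out$y[i], df_out$z[i]))) + 1L
    net$voxels[v[1], v[2], v[3]]
  }, logical(1))
  expect_false(any(inside_out))
  # determinism
  expect_identical(df, simulate_coordinate_table(sc))
})

test_that("synthetic expression plants signal genes and donor-unstable noise genes", {
  sc <- tiny_scenario(n_genes = 80L, n_signal_genes = 10L, n_regions = 16L,
                      unstable_fraction = 0.2)
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  set.seed(23)
  target <- region_vector(rnorm(16), seq_len(16))
  # gene_effect 1, no donor noise: perfect correlation with the target
  sc1 <- tiny_scenario(n_genes = 20L, n_signal_genes = 5L, n_regions = 16L,
                       gene_effect = 1, donor_noise_sd = 0, unstable_fraction = 0)
  d1 <- simulate_expression(sc1, target, atlas)
  expect_equal(abs(cor(d1[[1]]$values[, 1], target$values)), 1, tolerance = 1e-10)
  # gene_effect 0: no systematic correlation
  sc0 <- tiny_scenario(n_genes = 20L, n_signal_genes = 5L, n_regions = 16L,
                       gene_effect = 0, rng_seed = 31L)
  d0 <- simulate_expression(sc0, target, atlas)
  expect_lt(max(abs(cor(d0[[1]]$values[, 1:5], target$values))), 0.6)
  # the similarity filter drops the planted unstable genes
  donors <- simulate_expression(sc, target, atlas)
  out <- filter_genes_by_donor_similarity(donors, 0.1)
  unstable <- attr(donors, "unstable_genes")
  expect_gt(length(unstable), 0)
  # the filter is statistical: a stray unstable gene can clear 0.1 by chance
  # on 16 regions, but the bulk must be dropped
  expect_lte(sum(unstable %in% out$genes), ceiling(0.1 * length(unstable)))
  expect_true(all(attr(donors, "signal_genes") %in% out$genes))
  # determinism
  donors2 <- simulate_expression(sc, target, atlas)
  expect_identical(donors[[2]]$values, donors2[[2]]$values)
})

test_that("synthetic receptor maps encode the planted linear model", {
  sc <- tiny_scenario(n_regions = 16L)
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  target <- parcellate_map(planted_network(sc, g), atlas)
  # noiseless: OLS on the raw profiles recovers the planted weights exactly
  scn <- tiny_scenario(n_regions = 16L, receptor_r2 = 1)
  tr <- simulate_receptor_maps(scn, target, atlas)
  prof <- attr(tr, "system_profiles")
  X <- vapply(prof, function(p) p$values, numeric(16))
  fit <- lm(target$values ~ X)
  expect_equal(unname(coef(fit)[-1]), c(0, -0.24, 0, 0.33, 0), tolerance = 1e-6)
  # splitting one receptor into two cohorts averages back exactly
  d2 <- Filter(function(m) m$receptor == "D2", tr)
  expect_length(d2, 2L)
  avg <- weighted_tracer_average(d2)
  expect_lt(max(abs(avg$values - volumize_region_vector(prof$dopamine, atlas))),
            1e-10)
  # all-zero weights: target unrelated to the receptors
  scz <- tiny_scenario(n_regions = 16L,
                       receptor_weights = c(dopamine = 0, GABA = 0, glutamate = 0,
                                            noradrenaline = 0, serotonin = 0))
  trz <- simulate_receptor_maps(scz, target, atlas)
  sysz <- build_system_maps(trz, atlas)
  fz <- fit_receptor_model(target, sysz)
  expect_lt(fz$r2, 0.5)
  expect_gt(fz$f_stat$p, 0.01)
})
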