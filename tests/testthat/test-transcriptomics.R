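make_donors <- function(R = 30, G = 8, D = 3, seed = 9) {
  set.seed(seed)
  base <- matrix(rnorm(R * G), R, G)
  lapply(seq_len(D), function(d)
    expression_matrix(base + 0.5 * matrix(rnorm(R * G), R, G),
                      regions = seq_len(R),
                      genes = sprintf("g%02d", seq_len(G)),
                      donor_id = paste0("d", d)))
}

test_that("donor-similarity filter scores genes by mean pairwise correlation, strictly", {
  donors <- make_donors()
  out <- filter_genes_by_donor_similarity(donors, threshold = 0.1)
  sim <- attr(out, "similarity")
  # oracle: mean over donor pairs of cor() per gene
  for (gi in c(1, 4, 8)) {
    prof <- sapply(donors, function(d) d$values[, gi])
    cors <- cor(prof)[upper.tri(diag(3))]
    expect_equal(unname(sim[gi]), mean(cors), tolerance = 1e-12)
  }
  expect_setequal(out$genes, names(sim)[sim > 0.1])
  # averaged values
  gkeep <- match(out$genes[1], donors[[1]]$genes)
  expect_equal(out$values[, 1],
               (donors[[1]]$values[, gkeep] + donors[[2]]$values[, gkeep] +
                  donors[[3]]$values[, gkeep]) / 3)
  # identical donors: similarity exactly 1
  same <- lapply(1:2, function(d)
    expression_matrix(donors[[1]]$values, donors[[1]]$regions, donors[[1]]$genes))
  out1 <- filter_genes_by_donor_similarity(same, threshold = 0.5)
  expect_equal(length(out1$genes), 8L)
  # a gene whose similarity equals the threshold exactly is dropped (strict >)
  thr <- unname(attr(out1, "similarity")[1])
  expect_error(filter_genes_by_donor_similarity(same, threshold = thr),
               "no genes pass")
  expect_error(filter_genes_by_donor_similarity(donors[1]), "2 donors")
})

test_that("parcellation averages voxels within regions, honoring hemisphere filters", {
  sc <- tiny_scenario()
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  # constant map: every region equals the constant
  cm <- parcellate_map(stat_map(g, rep(3.5, n_voxels(g)), kind = "z"), atlas)
  expect_equal(cm$values, rep(3.5, atlas$n_regions))
  # hand-built two-voxel region
  vals <- numeric(n_voxels(g))
  r1 <- which(as.integer(atlas$labels) == 1)
  vals[r1] <- 0; vals[r1[1]] <- 1; vals[r1[2]] <- 3
  pm <- parcellate_map(stat_map(g, vals, kind = "z"), atlas)
  expect_equal(pm$values[1], (1 + 3 + sum(rep(0, length(r1) - 2))) / length(r1))
  # hemisphere filter keeps half the regions
  left <- parcellate_map(cm_map <- stat_map(g, rep(1, n_voxels(g)), kind = "z"),
                         atlas, hemisphere = "L")
  expect_equal(length(left$values), atlas$n_regions / 2)
  expect_true(all(atlas$hemisphere[left$regions] == "L"))
})

test_that("PLS1 weights equal the normalized X'y closed form", {
  set.seed(12)
  R <- 40; G <- 25
  X <- matrix(rnorm(R * G), R, G, dimnames = list(NULL, sprintf("g%02d", 1:G)))
  y <- rnorm(R)
  fit <- pls1_fit(X, y)
  # oracle: z-score, crossprod, normalize
  Xz <- scale(X); yz <- as.numeric(scale(y))
  w_oracle <- as.numeric(crossprod(Xz, yz)); w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_lt(max(abs(abs(fit$weights) - abs(w_oracle))), 1e-10)
  expect_lt(sum(abs(fit$weights - w_oracle)), 1e-8)  # same direction, not just magnitude
  expect_gte(fit$var_explained, 0); expect_lte(fit$var_explained, 1)
  # one gene equal to y plus one exactly orthogonal gene: y takes all the weight
  o <- resid(lm(rnorm(R) ~ y))  # sample-orthogonal to y by construction
  f1 <- pls1_fit(cbind(y = y, o = o), y)
  expect_equal(unname(abs(f1$weights["y"])), 1, tolerance = 1e-10)
  expect_equal(f1$var_explained, 1, tolerance = 1e-10)
  # two orthogonal genes, response equal to the first
  a <- rep(c(1, -1), 20); b <- rep(c(1, 1, -1, -1), 10)
  f2 <- pls1_fit(cbind(a = a, b = b), a)
  expect_equal(unname(abs(f2$weights)), c(1, 0), tolerance = 1e-12)
  expect_error(pls1_fit(X, rep(2, R)), "constant")
})

test_that("PLS1 agrees with an established PLS implementation on component 1", {
  skip_if_not_installed("mixOmics")
  set.seed(77)
  R <- 30; G <- 12
  X <- matrix(rnorm(R * G), R, G, dimnames = list(NULL, sprintf("g%02d", 1:G)))
  y <- as.numeric(scale(X[, 1] + 0.5 * rnorm(R)))
  ours <- pls1_fit(X, y)
  ref <- mixOmics::pls(scale(X), y, ncomp = 1, scale = FALSE, mode = "regression")
  w_ref <- as.numeric(ref$loadings$X[, 1])
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  if (sum(w_ref * ours$weights) < 0) w_ref <- -w_ref
  expect_equal(unname(ours$weights), w_ref, tolerance = 1e-8)
})

test_that("MSR surrogates preserve moments and spatial autocorrelation", {
  sc <- tiny_scenario(n_regions = 16L)
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  ctr <- atlas$centroids
  # an autocorrelated map over the centroids
  set.seed(31)
  d2 <- as.matrix(dist(ctr))^2
  K <- exp(-d2 / (2 * 14^2)); K <- K / rowSums(K)
  y <- region_vector(as.numeric(K %*% rnorm(16)) + 2, seq_len(16))
  surr <- msr_surrogates(y, atlas, n_surrogates = 60, rng_seed = 5)
  expect_length(surr, 60)
  for (s in surr[1:10]) {
    expect_equal(mean(s), mean(y$values), tolerance = 1e-8)
    expect_equal(var(s), var(y$values), tolerance = 1e-8)
  }
  # autocorrelation preservation: surrogate Moran's I hugs the observed value
  i_obs <- moran_i(y, atlas)
  i_surr <- vapply(surr, moran_i, numeric(1), atlas = atlas)
  set.seed(6)
  i_perm <- replicate(200, moran_i(sample(y$values), ctr))
  expect_lt(abs(median(i_surr) - i_obs), sd(i_perm) / 2)
  # empty request, degenerate geometry
  expect_length(msr_surrogates(y, atlas, n_surrogates = 0), 0)
  bad <- rbind(ctr[1, ], ctr[1, ], ctr[2, ])
  expect_error(msr_surrogates(rnorm(3), bad, 5), "coincident")
})

test_that("spatial p-values follow the add-one counting rule", {
  expect_equal(spatial_p_value(10, rep(1, 99)), 1 / 100)
  expect_equal(spatial_p_value(0, rep(1, 50)), 1)
  expect_equal(spatial_p_value(5, rep(5, 9)), 1)  # ties count
  s <- c(rep(0.1, 90), rep(0.9, 9))
  p0 <- spatial_p_value(0.5, s)
  expect_lte(spatial_p_value(0.5, c(s, 0.2)), p0 + 1e-12)
  expect_error(spatial_p_value(1, numeric(0)), "at least one")
})

test_that("bootstrap gene z separates collinear genes from noise and flags degenerate SDs", {
  set.seed(8)
  R <- 60; G <- 10
  y <- rnorm(R)
  X <- matrix(rnorm(R * G), R, G,
              dimnames = list(NULL, sprintf("g%02d", 1:G)))
  X[, 1] <- y + 0.05 * rnorm(R)       # near-collinear with the response
  X[, 2] <- y                          # exactly the response: degenerate SD
  X[, 3] <- 2                          # constant: no signal, zero weight
  z <- bootstrap_gene_z(X, y, n_boot = 200, rng_seed = 13)
  expect_gt(abs(z[1]), 10)
  expect_gt(z[2], 1e6)                 # bootstrap SD collapses to rounding noise
  expect_equal(unname(z[3]), 0)        # flagged degenerate, not spuriously infinite
  expect_gte(attr(z, "n_degenerate"), 1L)
  expect_lt(max(abs(z[4:10])), 5)
})

test_that("gene selection splits by sign at the threshold with FDR bookkeeping", {
  z <- c(a = 4.0, b = -4.0, c = 0.1)
  sel <- select_genes(z, 3.69)
  expect_equal(sel$positive, "a")
  expect_equal(sel$negative, "b")
  expect_equal(nrow(sel$table), 3L)
  sel0 <- select_genes(c(a = 0, b = 0), 3.69)
  expect_length(sel0$positive, 0); expect_length(sel0$negative, 0)
  selt <- select_genes(z, 0)
  expect_setequal(c(selt$positive, selt$negative), c("a", "b", "c"))
})

test_that("BH matches brute-force step-up on small vectors", {
  brute_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    ok <- which(p[o] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(sum(bh$reject), 3L)
  # only the smallest p survives here: 0.03 > 0.05 * 2/5 stops the step-up
  expect_equal(sum(benjamini_hochberg(c(0.001, 0.03, 0.2, 0.6, 0.9), 0.05)$reject), 1L)
  expect_equal(sum(benjamini_hochberg(rep(1, 6), 0.05)$reject), 0L)
  expect_true(benjamini_hochberg(0.04, 0.05)$reject)
  set.seed(15)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    res <- benjamini_hochberg(p, 0.05)
    expect_equal(res$reject, brute_bh(p, 0.05))
    expect_equal(res$qvalues, p.adjust(p, "BH"))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric ORA gives extreme p for perfect overlap and 1 for certainty", {
  bg <- sprintf("g%03d", 1:100)
  gs <- bg[1:10]
  ann <- list(hit = gs, miss = bg[50:60], all = bg)
  out <- hypergeom_ora(gs, ann, bg)
  expect_lt(out$p[out$term == "hit"], 1e-10)
  expect_equal(out$p[out$term == "all"], 1)      # certain event
  expect_equal(out$overlap[out$term == "miss"], 0L)
  expect_lte(max(out$p), 1)
  # background = set = term
  small <- sprintf("s%d", 1:5)
  expect_equal(hypergeom_ora(small, list(t = small), small)$p, 1)
  expect_error(hypergeom_ora(c(gs, "zzz"), ann, bg), "subset")
  expect_error(hypergeom_ora(gs, ann, character(0)), "empty")
})
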