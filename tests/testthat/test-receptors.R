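rv <- function(vals, name = "x") region_vector(vals, seq_along(vals), name = name)

sys_list <- function(X) {
  lapply(stats::setNames(colnames(X), colnames(X)), function(nm)
    region_vector(X[, nm], seq_len(nrow(X)), name = nm))
}

test_that("tracer averaging weights by cohort size", {
  g <- tiny_grid(4L)
  nv <- n_voxels(g)
  m1 <- tracer_map(rep(1, nv), g, "D2", "dopamine", 10)
  m4 <- tracer_map(rep(4, nv), g, "D2", "dopamine", 30)
  avg <- weighted_tracer_average(list(m1, m4))
  expect_equal(as.numeric(avg$values)[1], (10 * 1 + 30 * 4) / 40)  # 3.25
  expect_equal(avg$cohort_n, 40)
  expect_equal(weighted_tracer_average(list(m1))$values, m1$values)
  # equal cohorts reduce to the plain mean
  m2 <- tracer_map(rep(2, nv), g, "D2", "dopamine", 10)
  expect_equal(as.numeric(weighted_tracer_average(list(m1, m2))$values)[1], 1.5)
  bad <- tracer_map(rep(1, nv), g, "D1", "dopamine", 5)
  expect_error(weighted_tracer_average(list(m1, bad)), "mixed receptors")
})

test_that("system maps are z-normalized regional profiles", {
  sc <- tiny_scenario()
  g <- scenario_grid(sc)
  atlas <- make_toy_atlas(sc, g)
  set.seed(3)
  m <- tracer_map(rnorm(n_voxels(g)), g, "NAT", "noradrenaline", 77)
  sm <- system_map(list(m), atlas)
  expect_equal(mean(sm$values), 0, tolerance = 1e-10)
  expect_equal(sd(sm$values), 1, tolerance = 1e-10)
  expect_equal(sm$name, "noradrenaline")
  # degenerate: constant volume has zero regional variance
  flat <- tracer_map(rep(2, n_voxels(g)), g, "NAT", "noradrenaline", 10)
  expect_error(system_map(list(flat), atlas), "zero-variance")
  other <- tracer_map(rnorm(n_voxels(g)), g, "GABA_A", "GABA", 16)
  expect_error(system_map(list(m, other), atlas), "several systems")
})

test_that("the receptor OLS recovers noiseless planted coefficients", {
  set.seed(30)
  R <- 40
  X <- matrix(rnorm(R * 5), R, 5)
  colnames(X) <- c("dopamine", "GABA", "glutamate", "noradrenaline", "serotonin")
  y <- 0.3 * X[, "noradrenaline"] - 0.2 * X[, "GABA"]
  fit <- suppressWarnings(fit_receptor_model(rv(y), sys_list(X)))  # exact fit
  expect_equal(unname(fit$betas[-1]),
               c(0, -0.2, 0, 0.3, 0), tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)
  # single-predictor toy solved by normal equations
  x1 <- c(1, 2, 3, 4, 5, 6); y1 <- c(2, 2, 4, 5, 4, 7)
  slope <- sum((x1 - mean(x1)) * (y1 - mean(y1))) / sum((x1 - mean(x1))^2)
  f1 <- lm(y1 ~ x1)
  expect_equal(unname(coef(f1)[2]), slope)
  # rank-deficient design names the collinear column
  Xc <- cbind(X[, 1:4], serotonin = X[, "dopamine"])
  expect_error(fit_receptor_model(rv(0.3 * Xc[, 1] + rnorm(R)), sys_list(Xc)),
               "serotonin")
  expect_error(fit_receptor_model(rv(y[1:6]), sys_list(X[1:6, ])), "10 regions")
})

test_that("null receptor fits give calibrated F-test rejections", {
  set.seed(99)
  R <- 60; rejected <- 0; nrep <- 200
  for (i in seq_len(nrep)) {
    X <- matrix(rnorm(R * 5), R, 5)
    colnames(X) <- c("dopamine", "GABA", "glutamate", "noradrenaline", "serotonin")
    fit <- fit_receptor_model(rv(rnorm(R)), sys_list(X))
    rejected <- rejected + (fit$f_stat$p <= 0.05)
  }
  expect_lte(rejected / nrep, 0.08)
})

test_that("LMG matches brute-force ordering enumeration and known identities", {
  brute_lmg <- function(y, X) {
    p <- ncol(X)
    r2 <- function(s) if (!length(s)) 0 else {
      f <- lm.fit(cbind(1, X[, s, drop = FALSE]), y)
      1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    }
    perms <- as.matrix(expand.grid(rep(list(1:p), p)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == p), , drop = FALSE]
    contrib <- numeric(p)
    for (r in seq_len(nrow(perms))) {
      ord <- perms[r, ]
      for (k in seq_len(p)) {
        before <- if (k > 1) ord[1:(k - 1)] else integer(0)
        contrib[ord[k]] <- contrib[ord[k]] + r2(c(before, ord[k])) - r2(before)
      }
    }
    contrib / nrow(perms)
  }
  set.seed(41)
  R <- 30
  X <- matrix(rnorm(R * 5), R, 5)
  colnames(X) <- c("dopamine", "GABA", "glutamate", "noradrenaline", "serotonin")
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(R)
  res <- lmg_relative_importance(rv(y), sys_list(X))
  expect_equal(unname(res$contributions), brute_lmg(y, X), tolerance = 1e-10)
  expect_equal(sum(res$contributions), res$r2, tolerance = 1e-8)
  expect_true(all(res$contributions >= -1e-12))
  # permutation invariance of the decomposition
  perm <- c(3, 1, 5, 2, 4)
  res2 <- lmg_relative_importance(rv(y), sys_list(X[, perm]))
  expect_equal(res2$contributions[colnames(X)], res$contributions[colnames(X)])
  # orthogonal predictors: contribution = squared simple correlation
  # (orthogonalize after centering so sample orthogonality is exact)
  n <- 16
  M <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  Xo <- scale(qr.Q(qr(M)))
  colnames(Xo) <- c("dopamine", "GABA", "serotonin")
  yo <- Xo %*% c(0.8, 0.3, 0) + 0.2 * rnorm(n)
  reso <- lmg_relative_importance(rv(as.numeric(yo)), sys_list(Xo))
  expect_equal(unname(reso$contributions),
               as.numeric(cor(yo, Xo))^2, tolerance = 1e-6)
  # single predictor gets the whole R^2
  res1 <- lmg_relative_importance(rv(y), sys_list(X[, 1, drop = FALSE]))
  expect_equal(unname(res1$contributions), res1$r2)
  # duplicated predictor splits its share evenly
  Xd <- cbind(a = X[, 1], b = X[, 1])
  resd <- anmapr:::.lmg(y, Xd)
  expect_equal(unname(resd$contributions[1]), unname(resd$contributions[2]),
               tolerance = 1e-10)
  expect_equal(sum(resd$contributions), resd$r2, tolerance = 1e-10)
})

test_that("bootstrap relative importance yields non-negative CIs containing planted shares", {
  set.seed(55)
  R <- 80
  X <- matrix(rnorm(R * 5), R, 5)
  colnames(X) <- c("dopamine", "GABA", "glutamate", "noradrenaline", "serotonin")
  y <- 0.6 * X[, "noradrenaline"] - 0.4 * X[, "GABA"]   # noiseless
  truth <- lmg_relative_importance(rv(y), sys_list(X))$contributions
  out <- suppressWarnings(
    bootstrap_relative_importance(rv(y), sys_list(X), n_boot = 200,
                                  rng_seed = 2))
  expect_true(all(out$ci_lo >= 0))
  expect_true(all(out$ci_lo <= truth + 1e-8 & truth <= out$ci_hi + 1e-8))
  expect_equal(out$system, colnames(X))
  # BH across the five predictor p-values: oracle via p.adjust
  expect_equal(out$q, unname(p.adjust(out$p, "BH")))
})
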