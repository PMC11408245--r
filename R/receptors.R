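NEUROTRANSMITTER_SYSTEMS <- c("dopamine", "GABA", "glutamate",
                              "noradrenaline", "serotonin")

#' Tracer density map
#'
#' One PET receptor/transporter density image with its tracer cohort size.
#'
#' @param values Numeric array on the grid (density volume).
#' @param grid A [volume_grid()].
#' @param receptor Receptor/transporter name (e.g. `"5-HT1b"`, `"NAT"`,
#'   `"GABA_A"`).
#' @param system One of dopamine, GABA, glutamate, noradrenaline, serotonin.
#' @param cohort_n Number of participants in the tracer cohort (>= 1).
#' @return An object of class `tracer_map`.
#' @export
tracer_map <- function(values, grid, receptor, system, cohort_n) {
  system <- match.arg(system, NEUROTRANSMITTER_SYSTEMS)
  if (cohort_n < 1) stop("cohort_n must be >= 1")
  values <- as.numeric(values)
  stopifnot(length(values) == n_voxels(grid))
  dim(values) <- grid$shape
  structure(list(values = values, grid = grid, receptor = receptor,
                 system = system, cohort_n = as.numeric(cohort_n)),
            class = "tracer_map")
}

#' Participant-weighted average of tracer images
#'
#' Combines several images of the same receptor, weighting each voxelwise by
#' its cohort size; the result's cohort size is the total.
#'
#' @param maps List of [tracer_map()]s for one receptor on a shared grid.
#' @return A single [tracer_map()].
#' @export
weighted_tracer_average <- function(maps) {
  if (length(maps) < 1L) stop("need at least one tracer map")
  rec <- unique(vapply(maps, function(m) m$receptor, character(1)))
  if (length(rec) != 1L)
    stop("cannot average mixed receptors: ", paste(rec, collapse = ", "))
  g <- maps[[1]]$grid
  num <- array(0, g$shape); wsum <- 0
  for (m in maps) {
    stop_if_grid_mismatch(g, m$grid, "tracer maps")
    num <- num + m$cohort_n * m$values
    wsum <- wsum + m$cohort_n
  }
  tracer_map(num / wsum, g, rec, maps[[1]]$system, wsum)
}

#' Neurotransmitter system map
#'
#' Averages the receptor images of one system (unweighted across receptors;
#' apply [weighted_tracer_average()] per receptor first where a receptor has
#' several tracers), parcellates to atlas regions, and z-scores across
#' regions (mean 0, SD 1).
#'
#' @param maps List of [tracer_map()]s sharing one system.
#' @param atlas A [region_atlas()].
#' @return A z-normalized [region_vector()] named after the system.
#' @export
system_map <- function(maps, atlas) {
  sys <- unique(vapply(maps, function(m) m$system, character(1)))
  if (length(sys) != 1L)
    stop("maps span several systems: ", paste(sys, collapse = ", "))
  g <- maps[[1]]$grid
  acc <- array(0, g$shape)
  for (m in maps) {
    stop_if_grid_mismatch(g, m$grid, "tracer maps")
    acc <- acc + m$values
  }
  acc <- acc / length(maps)
  rv <- parcellate_map(stat_map(g, acc, kind = "z"), atlas)
  if (anyNA(rv$values)) stop("system map has regions without voxels")
  if (stats::sd(rv$values) == 0)
    stop("zero-variance regional profile for system ", sys)
  region_vector(as.numeric(scale(rv$values)), rv$regions, name = sys,
                atlas_name = atlas$name)
}

.systems_matrix <- function(ov, systems) {
  ovv <- if (inherits(ov, "region_vector")) ov else region_vector(ov, seq_along(ov))
  X <- vapply(systems, function(s) align_regions(s, ovv$regions),
              numeric(length(ovv$regions)))
  colnames(X) <- vapply(systems, function(s) s$name, character(1))
  list(y = ovv$values, X = X)
}

#' Multivariate regression of the consensus map on neurotransmitter systems
#'
#' Ordinary least squares with intercept:
#' Ov = b0 + b1 dopamine + b2 GABA + b3 glutamate + b4 noradrenaline +
#' b5 serotonin + error, where Ov is the regional overlap value. Errors on a
#' rank-deficient design, naming the collinear predictors.
#'
#' @param ov A [region_vector()] of regional overlap values.
#' @param systems Named list of z-normalized system [region_vector()]s.
#' @return A `receptor_fit`: `betas` (with intercept), `p_values` (per
#'   predictor), `r2`, `adj_r2`, `f_stat` (value, df1, df2, p), and the
#'   underlying `lm` fit.
#' @export
fit_receptor_model <- function(ov, systems) {
  d <- .systems_matrix(ov, systems)
  if (length(d$y) < 10L) stop("need at least 10 regions")
  df <- data.frame(ov = d$y, d$X, check.names = FALSE)
  mm <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrk <- qr(mm)
  if (qrk$rank < ncol(mm)) {
    bad <- colnames(mm)[qrk$pivot[(qrk$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(ov ~ ., data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    betas = stats::coef(fit),
    p_values = sm$coefficients[-1, 4],
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    f_stat = list(value = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
                  p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    lm = fit
  ), class = "receptor_fit")
}

#' @export
print.receptor_fit <- function(x, ...) {
  cat(sprintf("<receptor_fit> adj R2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              x$adj_r2, x$f_stat$df1, x$f_stat$df2, x$f_stat$value, x$f_stat$p))
  print(round(x$betas, 4))
  invisible(x)
}

# R^2 of y on predictor subset (rank-tolerant; used by the LMG decomposition)
.subset_r2 <- function(y, X, subset) {
  if (!length(subset)) return(0)
  f <- stats::lm.fit(cbind(1, X[, subset, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative importance decomposition
#'
#' Decomposes the linear model's R^2 into non-negative per-predictor shares:
#' each predictor's share is its incremental R^2 when entering the model,
#' averaged over all p! predictor orderings (computed exactly via the subset
#' weighting identity). Shares sum to the unadjusted R^2.
#'
#' @inheritParams fit_receptor_model
#' @return List with `contributions` (sum = R^2), `percentages`
#'   (contributions / R^2 * 100), and `r2`.
#' @export
lmg_relative_importance <- function(ov, systems) {
  d <- .systems_matrix(ov, systems)
  .lmg(d$y, d$X)
}

.lmg <- function(y, X) {
  p <- ncol(X)
  if (p > 8L) stop("exact LMG enumeration supports at most 8 predictors")
  subsets <- lapply(0:(2^p - 1), function(code) which(bitwAnd(code, 2^(0:(p - 1))) > 0))
  r2s <- vapply(subsets, function(s) .subset_r2(y, X, s), numeric(1))
  codes <- 0:(2^p - 1)
  contrib <- numeric(p)
  for (i in seq_len(p)) {
    without_i <- codes[bitwAnd(codes, 2^(i - 1)) == 0]
    for (code in without_i) {
      s <- length(subsets[[code + 1]])
      wt <- exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
      contrib[i] <- contrib[i] +
        wt * (r2s[code + 2^(i - 1) + 1] - r2s[code + 1])
    }
  }
  names(contrib) <- colnames(X)
  r2 <- r2s[2^p]
  list(contributions = contrib,
       percentages = if (r2 > 0) 100 * contrib / r2 else contrib * NA,
       r2 = r2)
}

#' Bootstrap confidence intervals for relative importance
#'
#' Region-resampled percentile intervals for each system's LMG contribution,
#' plus BH-FDR across the five predictors' OLS p-values from the full-data
#' fit.
#'
#' @inheritParams fit_receptor_model
#' @param n_boot Bootstrap resamples (>= 100).
#' @param rng_seed Integer seed.
#' @param conf Interval coverage (default 0.95).
#' @param fdr_q FDR level for the predictor p-values.
#' @return Data frame (system, beta, p, q, significant, rel_importance,
#'   pct_of_r2, ci_lo, ci_hi).
#' @export
bootstrap_relative_importance <- function(ov, systems, n_boot = 5000,
                                          rng_seed = 1, conf = 0.95,
                                          fdr_q = 0.05) {
  if (n_boot < 100L) stop("need at least 100 bootstrap resamples")
  d <- .systems_matrix(ov, systems)
  full_fit <- fit_receptor_model(ov, systems)
  full_lmg <- .lmg(d$y, d$X)
  R <- length(d$y)
  set.seed(rng_seed)
  bs <- matrix(NA_real_, n_boot, ncol(d$X))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(R, R, replace = TRUE)
    bs[b, ] <- .lmg(d$y[idx], d$X[idx, , drop = FALSE])$contributions
  }
  alpha <- (1 - conf) / 2
  ci <- apply(bs, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  fdr <- benjamini_hochberg(full_fit$p_values, q = fdr_q)
  data.frame(
    system = colnames(d$X),
    beta = full_fit$betas[-1],
    p = full_fit$p_values,
    q = fdr$qvalues,
    significant = fdr$reject,
    rel_importance = full_lmg$contributions,
    pct_of_r2 = full_lmg$percentages,
    ci_lo = ci[1, ],
    ci_hi = ci[2, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
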