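#' Subject resting-state time series
#'
#' Holds one subject's preprocessed volumetric time series in compact
#' timepoints x in-mask-voxels form.
#'
#' @param data T x V numeric matrix (timepoints by in-mask voxels; columns
#'   follow `which(brain_mask$voxels)` order).
#' @param grid A [volume_grid()].
#' @param mask A [brain_mask()] with V voxels set.
#' @param subject_id Identifier string.
#' @return An object of class `subject_time_series`.
#' @export
subject_time_series <- function(data, grid, mask, subject_id = "s1") {
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("need at least 3 timepoints")
  if (ncol(data) != mask_size(mask))
    stop("data columns must equal brain mask voxel count")
  if (!all(is.finite(data))) stop("time series contain non-finite values")
  stop_if_grid_mismatch(grid, mask$grid, "subject data and brain mask")
  structure(list(grid = grid, data = data, brain_mask = mask,
                 subject_id = as.character(subject_id)),
            class = "subject_time_series")
}

#' Mean time series over a seed
#'
#' Unweighted per-timepoint mean over the voxels in `seed` that fall inside
#' the subject's brain mask.
#'
#' @param subject A [subject_time_series()].
#' @param seed A [brain_mask()].
#' @param label Experiment label used in error messages.
#' @return Numeric vector of length T.
#' @export
seed_mean_timeseries <- function(subject, seed, label = "seed") {
  stop_if_grid_mismatch(subject$grid, seed$grid, "subject and seed")
  inmask <- seed$voxels[subject$brain_mask$voxels]
  if (!any(inmask))
    stop(sprintf("seed '%s' does not intersect the brain mask", label))
  rowMeans(subject$data[, inmask, drop = FALSE])
}

#' Seed-to-voxel correlation map for one subject
#'
#' Pearson correlation between the seed mean time series and every in-mask
#' voxel's series. Voxels with zero temporal variance get r = 0; their count
#' is reported via a message.
#'
#' @inheritParams seed_mean_timeseries
#' @return A [stat_map()] of kind `"r"` (zero outside the brain mask).
#' @export
seed_fc_map <- function(subject, seed, label = "seed") {
  s <- seed_mean_timeseries(subject, seed, label)
  if (stats::sd(s) == 0)
    stop(sprintf("seed '%s' has a zero-variance mean time series", label))
  r <- suppressWarnings(as.numeric(stats::cor(subject$data, s)))
  n_bad <- sum(!is.finite(r))
  if (n_bad > 0) {
    message(n_bad, " zero-variance voxel(s) set to r = 0")
    r[!is.finite(r)] <- 0
  }
  vals <- numeric(n_voxels(subject$grid))
  vals[which(subject$brain_mask$voxels)] <- r
  stat_map(subject$grid, vals, kind = "r")
}

#' Fisher z-transform of a correlation map
#'
#' Elementwise atanh; correlations at exactly +/-1 are clipped to
#' 1 - 1e-7 in magnitude first (with a message) so the transform stays finite.
#'
#' @param map A [stat_map()] of kind `"r"`.
#' @return A [stat_map()] of kind `"z"`.
#' @export
fisher_z <- function(map) {
  if (!inherits(map, "stat_map") || map$kind != "r")
    stop("fisher_z expects a stat_map of kind 'r'")
  v <- map$values
  clip <- abs(v) >= 1
  if (any(clip)) {
    message(sum(clip), " |r| = 1 value(s) clipped before atanh")
    v[clip] <- sign(v[clip]) * (1 - 1e-7)
  }
  stat_map(map$grid, atanh(v), kind = "z")
}

#' One-sample t-map across subjects
#'
#' Voxelwise one-sample t test of subject z-maps against zero:
#' t = mean / (sd / sqrt(n)), df = n - 1. Voxels with zero across-subject
#' variance get t = 0 and are counted in the `n_degenerate` attribute.
#'
#' @param zmaps List of [stat_map()]s of kind `"z"` on a shared grid.
#' @return A [stat_map()] of kind `"t"` with `df = n - 1`.
#' @export
one_sample_tmap <- function(zmaps) {
  n <- length(zmaps)
  if (n < 2L) stop("need at least 2 z-maps")
  for (m in zmaps) {
    if (m$kind != "z") stop("one_sample_tmap expects z-maps")
    stop_if_grid_mismatch(zmaps[[1]]$grid, m$grid)
  }
  x <- vapply(zmaps, function(m) as.numeric(m$values), numeric(n_voxels(zmaps[[1]]$grid)))
  x <- matrix(x, ncol = n)  # single-voxel grids collapse vapply to a vector
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sdv <- sqrt(ss / (n - 1))
  tt <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  out <- stat_map(zmaps[[1]]$grid, tt, kind = "t", df = n - 1L)
  attr(out, "n_degenerate") <- sum(sdv == 0 & mu != 0)
  out
}

#' Binarize a t-map at a threshold
#'
#' Strict one-tailed cut: voxels with t > `t_thresh` (positive tail only;
#' negative connectivity is discarded).
#'
#' @param map A [stat_map()] of kind `"t"`.
#' @param t_thresh Threshold.
#' @return A [brain_mask()].
#' @export
threshold_binarize <- function(map, t_thresh = 3) {
  if (!inherits(map, "stat_map") || map$kind != "t")
    stop("threshold_binarize expects a stat_map of kind 't'")
  brain_mask(map$grid, map$values > t_thresh)
}

#' Experiment-level t-maps from a normative connectome
#'
#' Streams subjects one at a time: for each subject computes the
#' seed-to-voxel r-map for every combined seed, Fisher z-transforms it, and
#' accumulates running sums, so the full subject set is never held in memory.
#' Then forms the per-experiment one-sample t-map against zero.
#'
#' @param subject_source Either a list of [subject_time_series()] or a
#'   function `f(i)` returning subject `i` (e.g. [subject_generator()] or a
#'   NIfTI-backed loader).
#' @param n_subjects Number of subjects (defaults to `length(subject_source)`
#'   when a list is given).
#' @param seeds Named list of combined-seed [brain_mask()]s, one per
#'   experiment.
#' @return Named list of t [stat_map()]s with `df = n_subjects - 1`.
#' @export
compute_experiment_tmaps <- function(subject_source, seeds,
                                     n_subjects = if (is.list(subject_source)) length(subject_source) else NULL) {
  if (is.null(n_subjects)) stop("n_subjects required when subject_source is a function")
  if (n_subjects < 2L) stop("need at least 2 subjects")
  get_subject <- if (is.function(subject_source)) subject_source else
    function(i) subject_source[[i]]
  sums <- NULL
  sumsq <- NULL
  grid <- NULL
  for (i in seq_len(n_subjects)) {
    subj <- get_subject(i)
    if (is.null(grid)) {
      grid <- subj$grid
      nv <- n_voxels(grid)
      sums <- matrix(0, nv, length(seeds))
      sumsq <- matrix(0, nv, length(seeds))
    }
    for (e in seq_along(seeds)) {
      z <- as.numeric(fisher_z(seed_fc_map(subj, seeds[[e]],
                                           label = names(seeds)[e] %||% e))$values)
      sums[, e] <- sums[, e] + z
      sumsq[, e] <- sumsq[, e] + z^2
    }
  }
  n <- n_subjects
  out <- lapply(seq_along(seeds), function(e) {
    mu <- sums[, e] / n
    ss <- pmax(sumsq[, e] - n * mu^2, 0)
    sdv <- sqrt(ss / (n - 1))
    tt <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
    stat_map(grid, tt, kind = "t", df = n - 1L)
  })
  names(out) <- names(seeds)
  out
}
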