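#' Overlap counts across binarized experiment maps
#'
#' @param masks List of [brain_mask()]s on a shared grid, one per experiment.
#' @return An `overlap_map`: per-voxel count of contributing experiments,
#'   with `n_experiments = length(masks)`.
#' @export
overlap_counts <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask")
  g <- masks[[1]]$grid
  counts <- array(0L, g$shape)
  for (m in masks) {
    stop_if_grid_mismatch(g, m$grid, "overlapped masks")
    counts <- counts + m$voxels
  }
  structure(list(grid = g, counts = counts, n_experiments = length(masks)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> E = %d, max count = %d\n",
              x$n_experiments, max(x$counts)))
  invisible(x)
}

#' Consensus network mask from an overlap map
#'
#' Keeps voxels contributed by at least `ceiling(fraction * E)` experiments:
#' with E = 11 and fraction 0.6 that is count >= 7, matching the
#' strict-majority reading of a 60 percent overlap threshold.
#'
#' @param overlap An overlap map from [overlap_counts()].
#' @param fraction Fraction of experiments required, in (0, 1].
#' @return A [brain_mask()].
#' @export
consensus_mask <- function(overlap, fraction = 0.6) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * overlap$n_experiments - 1e-9)
  brain_mask(overlap$grid, overlap$counts >= k)
}

#' Dice similarity of two binary masks
#'
#' 2|A n B| / (|A| + |B|). Two empty masks are defined as identical
#' (Dice = 1) with a message, so degenerate sweeps do not fail.
#'
#' @param a,b [brain_mask()]s on a shared grid.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) {
    message("dice of two empty masks defined as 1")
    return(1)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Leave-one-experiment-out stability
#'
#' Rebuilds the consensus from each subset of E - 1 binarized maps at the
#' same overlap fraction and reports its Dice similarity with the full-E
#' consensus.
#'
#' @param masks Named list of binarized experiment [brain_mask()]s (E >= 3).
#' @param fraction Overlap fraction, as in [consensus_mask()].
#' @return Data frame with columns `left_out_id` and `dice`.
#' @export
leave_one_experiment_out <- function(masks, fraction = 0.6) {
  E <- length(masks)
  if (E < 3L) stop("leave-one-out needs at least 3 experiments")
  full <- consensus_mask(overlap_counts(masks), fraction)
  ids <- names(masks) %||% as.character(seq_len(E))
  d <- vapply(seq_len(E), function(i) {
    reduced <- consensus_mask(overlap_counts(masks[-i]), fraction)
    dice(reduced, full)
  }, numeric(1))
  data.frame(left_out_id = ids, dice = d, stringsAsFactors = FALSE)
}

#' Robustness sweep over analysis parameters
#'
#' Perturbs, one at a time, the overlap fraction, the t threshold, and the
#' seed radius, and reports the Dice similarity of each perturbed consensus
#' with the reference consensus (reference defaults: 4 mm seeds, t > 3,
#' fraction 0.6).
#'
#' @param tmaps_by_radius Named list (names = radii in mm, as character) of
#'   lists of experiment-level t [stat_map()]s; must contain the reference
#'   radius.
#' @param fractions Overlap fractions to sweep.
#' @param t_thresholds t thresholds to sweep.
#' @param ref_radius,ref_fraction,ref_t Reference configuration.
#' @return Tidy data frame with columns `parameter`, `value`, `dice`.
#' @export
robustness_sweep <- function(tmaps_by_radius,
                             fractions = c(0.5, 0.6, 0.7),
                             t_thresholds = c(2.5, 3, 3.5),
                             ref_radius = "4", ref_fraction = 0.6, ref_t = 3) {
  ref_radius <- as.character(ref_radius)
  if (!ref_radius %in% names(tmaps_by_radius))
    stop("reference radius ", ref_radius, " missing from tmaps_by_radius")
  binarize_all <- function(tmaps, thr) lapply(tmaps, threshold_binarize, t_thresh = thr)
  ref_masks <- binarize_all(tmaps_by_radius[[ref_radius]], ref_t)
  ref <- consensus_mask(overlap_counts(ref_masks), ref_fraction)
  rows <- list()
  for (f in fractions) {
    m <- consensus_mask(overlap_counts(ref_masks), f)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "fraction", value = f,
                                            dice = dice(m, ref))
  }
  for (tt in t_thresholds) {
    m <- consensus_mask(overlap_counts(binarize_all(tmaps_by_radius[[ref_radius]], tt)),
                        ref_fraction)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "t_threshold", value = tt,
                                            dice = dice(m, ref))
  }
  for (r in names(tmaps_by_radius)) {
    m <- consensus_mask(overlap_counts(binarize_all(tmaps_by_radius[[r]], ref_t)),
                        ref_fraction)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "radius", value = as.numeric(r),
                                            dice = dice(m, ref))
  }
  do.call(rbind, rows)
}
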