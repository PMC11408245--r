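#' Convert a t-map to a z-map
#'
#' Probability-preserving conversion z = qnorm(pt(t, df)) evaluated through
#' log tail probabilities, symmetrically for each tail, so that large |t|
#' does not saturate to +/-Inf.
#'
#' @param map A [stat_map()] of kind `"t"` with `df` set.
#' @return A [stat_map()] of kind `"z"`.
#' @export
t_to_z <- function(map) {
  if (!inherits(map, "stat_map") || map$kind != "t")
    stop("t_to_z expects a stat_map of kind 't'")
  if (is.null(map$df)) stop("t_to_z requires df")
  stat_map(map$grid, t_to_z_values(as.numeric(map$values), map$df), kind = "z")
}

t_to_z_values <- function(t, df) {
  z <- numeric(length(t))
  neg <- t <= 0
  # lower tail in log space for t <= 0, mirrored upper tail for t > 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(t[!neg], df, lower.tail = FALSE, log.p = TRUE),
                           lower.tail = TRUE, log.p = TRUE)
  z
}

#' Voxelwise mean of z-maps
#'
#' @param zmaps List of [stat_map()]s of kind `"z"` on a shared grid.
#' @return A [stat_map()] of kind `"z"`.
#' @export
group_mean_zmap <- function(zmaps) {
  if (length(zmaps) < 1L) stop("need at least one z-map")
  g <- zmaps[[1]]$grid
  acc <- array(0, g$shape)
  for (m in zmaps) {
    if (m$kind != "z") stop("group_mean_zmap expects z-maps")
    stop_if_grid_mismatch(g, m$grid)
    acc <- acc + m$values
  }
  stat_map(g, acc / length(zmaps), kind = "z")
}

#' ROI from atlas labels
#'
#' @param atlas A [region_atlas()].
#' @param labels Integer label IDs to include.
#' @param name ROI name.
#' @return An `roi_spec`: a named, non-empty [brain_mask()] plus provenance.
#' @export
roi_from_atlas <- function(atlas, labels, name = "roi") {
  vox <- array(atlas$labels %in% labels, dim(atlas$labels))
  if (!any(vox)) stop("ROI '", name, "' is empty on this atlas")
  structure(list(name = name, mask = brain_mask(atlas$grid, vox),
                 provenance = paste("atlas labels", paste(labels, collapse = ","))),
            class = "roi_spec")
}

#' Cohen's d between two maps inside an ROI
#'
#' Standardized difference of the two maps' voxel-value distributions within
#' the ROI: d = (mean_a - mean_b) / s_pooled, pooled SD with an
#' (n_a + n_b - 2) denominator.
#'
#' @param map_a,map_b [stat_map()]s on the ROI's grid.
#' @param roi An `roi_spec` from [roi_from_atlas()], or a [brain_mask()].
#' @return Cohen's d (numeric scalar) with attributes `n_vox`, `mean_a`,
#'   `mean_b`.
#' @export
roi_cohens_d <- function(map_a, map_b, roi) {
  mask <- if (inherits(roi, "roi_spec")) roi$mask else roi
  stop_if_grid_mismatch(map_a$grid, mask$grid, "map and ROI")
  stop_if_grid_mismatch(map_b$grid, mask$grid, "map and ROI")
  a <- as.numeric(map_a$values[mask$voxels])
  b <- as.numeric(map_b$values[mask$voxels])
  if (length(a) < 2L) stop("ROI must contain at least 2 voxels")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  structure(d, n_vox = length(a), mean_a = mean(a), mean_b = mean(b))
}

#' Specificity table over several ROIs
#'
#' @param map_a,map_b Group mean z [stat_map()]s (e.g. depression vs disease
#'   control).
#' @param rois List of `roi_spec`s.
#' @return Data frame with columns `roi`, `d`, `n_vox`, `mean_a`, `mean_b`.
#' @export
specificity_table <- function(map_a, map_b, rois) {
  do.call(rbind, lapply(rois, function(r) {
    d <- roi_cohens_d(map_a, map_b, r)
    data.frame(roi = r$name, d = as.numeric(d), n_vox = attr(d, "n_vox"),
               mean_a = attr(d, "mean_a"), mean_b = attr(d, "mean_b"),
               stringsAsFactors = FALSE)
  }))
}
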