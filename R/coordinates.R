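#' Lancaster ICBM/SPM-pose MNI-to-Talairach affine
#'
#' The published best-fit affine taking ICBM/MNI coordinates (SPM pose) to
#' Talairach space. Its inverse is the default Talairach-to-MNI transform
#' used by [tal2mni()].
#'
#' @return A 4x4 numeric matrix.
#' @export
icbm_spm2tal_matrix <- function() {
  matrix(c(
     0.9254,  0.0024, -0.0118, -1.0207,
    -0.0048,  0.9316, -0.0871, -1.7667,
     0.0152,  0.0883,  0.8924,  4.0926,
     0,       0,       0,       1
  ), nrow = 4, byrow = TRUE)
}

#' Convert Talairach coordinates to MNI
#'
#' Applies an affine Talairach-to-MNI transform to one focus or a matrix of
#' foci. The default transform is the inverse of the Lancaster ICBM/SPM-pose
#' MNI-to-Talairach affine ("tal2icbm", SPM variant); pass `transform` to use
#' a different convention. Foci already tagged MNI should not be passed here
#' (see [normalize_foci()]).
#'
#' @param focus Numeric length-3 vector (x, y, z in mm), or an n x 3 matrix.
#' @param transform 4x4 affine applied to the Talairach coordinates; defaults
#'   to `solve(icbm_spm2tal_matrix())`.
#' @return Coordinates of the same shape as the input, in MNI mm.
#' @examples
#' tal2mni(c(0, 0, 0))
#' @export
tal2mni <- function(focus, transform = solve(icbm_spm2tal_matrix())) {
  one <- is.null(dim(focus))
  m <- if (one) rbind(as.numeric(focus)) else as.matrix(focus)
  if (ncol(m) != 3L || !all(is.finite(m)))
    stop("invalid coordinate: foci must be finite x/y/z triples")
  stopifnot(is.matrix(transform), all(dim(transform) == c(4, 4)))
  out <- cbind(m, 1) %*% t(transform)
  out <- out[, 1:3, drop = FALSE]
  if (one) as.numeric(out) else out
}

#' Normalize an experiment's foci to grid (MNI) space
#'
#' MNI-tagged foci pass through unchanged; Talairach-tagged foci are mapped
#' by [tal2mni()].
#'
#' @param foci n x 3 matrix of world mm coordinates.
#' @param space `"MNI"` or `"Talairach"`.
#' @param transform Affine forwarded to [tal2mni()].
#' @return n x 3 matrix in MNI mm.
#' @export
normalize_foci <- function(foci, space = c("MNI", "Talairach"),
                           transform = solve(icbm_spm2tal_matrix())) {
  space <- match.arg(space)
  foci <- as.matrix(foci)
  if (!all(is.finite(foci))) stop("invalid coordinate: non-finite focus")
  if (space == "MNI") foci else tal2mni(foci, transform)
}

#' Spherical seed mask around a world coordinate
#'
#' Marks every voxel whose centre lies within Euclidean distance `radius`
#' (inclusive) of `center`, in world mm. A centre outside the grid bounding
#' box yields an empty mask with a warning, not an error.
#'
#' @param center Length-3 world mm coordinate.
#' @param radius Sphere radius in mm (>= 0).
#' @param grid A [volume_grid()].
#' @return A [brain_mask()].
#' @examples
#' g <- default_grid(20, 2)
#' mask_size(build_sphere_mask(c(0, 0, 0), 4, g))  # 33 voxels on a 2 mm grid
#' @export
build_sphere_mask <- function(center, radius, grid) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, radius >= 0)
  if (!all(is.finite(center))) stop("invalid coordinate: non-finite center")
  bb <- grid_bounding_box(grid)
  if (any(center < bb["lo", ] - radius) || any(center > bb["hi", ] + radius)) {
    warning(sprintf("sphere center (%.1f, %.1f, %.1f) lies outside the grid; empty mask",
                    center[1], center[2], center[3]))
    return(brain_mask(grid, array(FALSE, grid$shape)))
  }
  ctr <- voxel_centers(grid)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 + (ctr[, 3] - center[3])^2
  brain_mask(grid, d2 <= radius^2 + 1e-9)
}

#' Combined seed for one experiment
#'
#' Builds the union of per-focus spheres for one experiment's foci. Foci must
#' already be in grid space (apply [normalize_foci()] first). Errors if the
#' union is empty (all foci out of bounds).
#'
#' @param record An `experiment_record` (see [as_experiment_records()]), or any
#'   list with elements `foci` (n x 3 matrix) and optionally `study_id`,
#'   `task_label`.
#' @param radius Sphere radius in mm.
#' @param grid A [volume_grid()].
#' @return A [brain_mask()].
#' @export
combine_experiment_seed <- function(record, radius, grid) {
  foci <- as.matrix(record$foci)
  if (nrow(foci) == 0L) stop("experiment has no foci")
  vox <- array(FALSE, grid$shape)
  for (i in seq_len(nrow(foci))) {
    s <- build_sphere_mask(foci[i, ], radius, grid)
    vox <- vox | s$voxels
  }
  if (!any(vox))
    stop(sprintf("combined seed is empty for experiment %s / %s: all foci out of bounds",
                 record$study_id %||% "?", record$task_label %||% "?"))
  brain_mask(grid, vox)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a coordinate table
#'
#' Tab-separated, one row per focus, with a header row. Required columns:
#' `study_id`, `task_label`, `space` (MNI or Talairach), `x`, `y`, `z`;
#' optional group-size columns `n_case`, `n_control` (and any extras, which
#' are preserved). Experiments are keyed by `(study_id, task_label)`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of foci.
#' @export
read_coordinate_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("study_id", "task_label", "space", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coordinate table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$space %in% c("MNI", "Talairach")))
    stop("space column must be 'MNI' or 'Talairach'")
  df
}

#' Write a coordinate table
#'
#' @param df Data frame as returned by [read_coordinate_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coordinate_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a coordinate table into experiment records
#'
#' Groups foci by `(study_id, task_label)` and normalizes Talairach foci to
#' MNI. Each record carries the foci matrix (grid space), the space tag of
#' the source rows, and the per-study group sizes if present.
#'
#' @param df Coordinate table data frame.
#' @param transform Talairach-to-MNI affine, forwarded to [normalize_foci()].
#' @return A named list of `experiment_record` objects, keyed
#'   `"study_id|task_label"` in first-appearance order.
#' @export
as_experiment_records <- function(df, transform = solve(icbm_spm2tal_matrix())) {
  key <- paste(df$study_id, df$task_label, sep = "|")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    spaces <- unique(rows$space)
    foci <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      normalize_foci(rbind(as.numeric(rows[i, c("x", "y", "z")])),
                     space = rows$space[i], transform = transform)
    }))
    rec <- structure(list(
      study_id = rows$study_id[1],
      task_label = rows$task_label[1],
      space = if (length(spaces) == 1L) spaces else "MNI",
      foci = foci,
      n_case = if ("n_case" %in% names(rows)) rows$n_case[1] else NA_integer_,
      n_control = if ("n_control" %in% names(rows)) rows$n_control[1] else NA_integer_,
      n_hc = if ("n_hc" %in% names(rows)) rows$n_hc[1] else NA_integer_
    ), class = "experiment_record")
    if (!is.na(rec$n_case) && (rec$n_case < 0 || rec$n_control < 0))
      stop("group sizes must be non-negative")
    out[[k]] <- rec
  }
  out
}

#' Cohort sizes across studies
#'
#' Sums the per-study group-size columns of a coordinate table, counting each
#' study once (several experiments can come from one study and share its
#' groups), and counts the distinct experiments.
#'
#' @param df Coordinate table data frame.
#' @return A list with `n_experiments`, `n_studies`, `n_case`, `n_control`
#'   and (when the column is present) `n_hc`.
#' @export
cohort_sizes <- function(df) {
  first <- df[!duplicated(df$study_id), , drop = FALSE]
  list(
    n_experiments = length(unique(paste(df$study_id, df$task_label, sep = "|"))),
    n_studies = nrow(first),
    n_case = sum(first$n_case),
    n_control = sum(first$n_control),
    n_hc = if ("n_hc" %in% names(first)) sum(first$n_hc) else NA_integer_
  )
}
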