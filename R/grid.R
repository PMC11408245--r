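#' Volumetric sampling grid
#'
#' A `volume_grid` defines the common sampling space every map in an analysis
#' lives on: an integer voxel lattice plus a 4x4 affine mapping 0-based voxel
#' indices to world millimetre coordinates (MNI-style).
#'
#' @param shape Integer vector of length 3, voxels along each axis.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world mm.
#' @param space_label Free-text label for the world space, e.g. `"MNI152"`.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(20, 20, 20), affine = diag(c(2, 2, 2, 1)))
#' @export
volume_grid <- function(shape, affine, space_label = "MNI152") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- unclass(affine)
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)), all(is.finite(affine)))
  det_a <- det(affine)
  if (abs(det_a) < .Machine$double.eps * 100)
    stop("grid affine must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be strictly positive")
  structure(
    list(shape = shape, affine = affine, space_label = as.character(space_label)),
    class = "volume_grid"
  )
}

#' Default isotropic grid
#'
#' An isotropic grid with the world origin at the grid centre; the default
#' 2 mm, 91 x 109 x 91 configuration has an MNI152-like bounding box
#' (x from -90 to 90, y from -126 to 90, z from -72 to 108).
#'
#' @param shape Voxels per axis (length 1 or 3).
#' @param voxel_size Edge length in mm.
#' @param space_label Space tag stored on the grid.
#' @return A [volume_grid()].
#' @export
default_grid <- function(shape = c(91L, 109L, 91L), voxel_size = 2,
                         space_label = "MNI152") {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  aff <- diag(c(rep(voxel_size, 3), 1))
  # centre the world origin on the grid centre (MNI-like for the default box)
  if (identical(as.integer(shape), c(91L, 109L, 91L)) && voxel_size == 2) {
    aff[1:3, 4] <- c(-90, -126, -72)
  } else {
    aff[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  volume_grid(shape, aff, space_label)
}

#' @export
print.volume_grid <- function(x, ...) {
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<volume_grid> %s, %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$space_label, x$shape[1], x$shape[2], x$shape[3],
              vs[1], vs[2], vs[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "maps") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

#' Voxel-centre world coordinates
#'
#' @param grid A [volume_grid()].
#' @return An n_voxels x 3 matrix of world mm coordinates, rows in R array
#'   (first-axis-fastest) order.
#' @export
voxel_centers <- function(grid) {
  idx <- as.matrix(expand.grid(
    i = seq_len(grid$shape[1]) - 1L,
    j = seq_len(grid$shape[2]) - 1L,
    k = seq_len(grid$shape[3]) - 1L
  ))
  xyz1 <- cbind(idx, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' World mm to continuous 0-based voxel coordinates
#'
#' @param grid A [volume_grid()].
#' @param xyz Length-3 world coordinate in mm.
#' @return Length-3 numeric 0-based voxel coordinate.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind(c(as.numeric(xyz), 1))
  as.numeric(solve(grid$affine) %*% t(xyz))[1:3]
}

grid_bounding_box <- function(grid) {
  corners <- as.matrix(expand.grid(
    i = c(0, grid$shape[1] - 1L),
    j = c(0, grid$shape[2] - 1L),
    k = c(0, grid$shape[3] - 1L)
  ))
  w <- cbind(corners, 1) %*% t(grid$affine)
  rbind(lo = apply(w[, 1:3, drop = FALSE], 2, min),
        hi = apply(w[, 1:3, drop = FALSE], 2, max))
}

#' Binary voxel mask
#'
#' @param grid A [volume_grid()].
#' @param voxels Logical array with the grid's shape (or a logical vector of
#'   length `prod(shape)`).
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, voxels) {
  if (is.null(dim(voxels))) dim(voxels) <- grid$shape
  stopifnot(is.logical(voxels), identical(dim(voxels), as.integer(grid$shape)))
  structure(list(grid = grid, voxels = voxels), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d / %d voxels set\n", sum(x$voxels), n_voxels(x$grid)))
  invisible(x)
}

#' Number of voxels set in a mask
#' @param mask A [brain_mask()].
#' @return Integer count.
#' @export
mask_size <- function(mask) sum(mask$voxels)

mask_union <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  brain_mask(a$grid, a$voxels | b$voxels)
}

#' Per-voxel statistic volume
#'
#' Wraps one statistical volume (correlation, Fisher-z or t values) together
#' with its grid, statistic kind, and degrees of freedom where applicable.
#'
#' @param grid A [volume_grid()].
#' @param values Numeric array with the grid's shape (or a vector of matching
#'   length).
#' @param kind One of `"r"`, `"z"`, `"t"`.
#' @param df Degrees of freedom; required for `kind = "t"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(grid, values, kind = c("r", "z", "t"), df = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  stopifnot(length(values) == n_voxels(grid))
  dim(values) <- grid$shape
  if (kind == "r" && any(abs(values) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation map has values outside [-1, 1]")
  if (kind == "t") {
    if (is.null(df)) stop("t maps require df")
    if (df < 1) stop("t maps require df >= 1")
  }
  structure(list(grid = grid, values = values, kind = kind, df = df),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map kind=%s%s> range [%.4g, %.4g]\n", x$kind,
              if (!is.null(x$df)) paste0(", df=", x$df) else "",
              min(x$values), max(x$values)))
  invisible(x)
}
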