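#' Write a volume to NIfTI-1
#'
#' Masks are written as uint8, statistic volumes and atlases carry their
#' values unchanged; the grid affine is stored in both sform and qform.
#'
#' @param x A [brain_mask()], [stat_map()], [region_atlas()], or a plain
#'   numeric array plus `grid`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param grid Required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, grid = NULL) {
  if (inherits(x, "brain_mask")) {
    arr <- array(as.integer(x$voxels), x$grid$shape); grid <- x$grid
    im <- RNifti::asNifti(arr, datatype = "uint8")
  } else if (inherits(x, "stat_map")) {
    arr <- x$values; grid <- x$grid
    im <- RNifti::asNifti(arr)
  } else if (inherits(x, "region_atlas")) {
    arr <- x$labels; grid <- x$grid
    im <- RNifti::asNifti(arr, datatype = "int16")
  } else {
    if (is.null(grid)) stop("grid required for a bare array")
    im <- RNifti::asNifti(x)
  }
  aff <- grid$affine
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::qform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a 4D subject time series to NIfTI-1
#'
#' @param subject A [subject_time_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_nifti <- function(subject, path) {
  g <- subject$grid
  arr <- array(0, c(g$shape, nrow(subject$data)))
  idx <- which(subject$brain_mask$voxels)
  nv <- n_voxels(g)
  for (t in seq_len(nrow(subject$data)))
    arr[idx + (t - 1) * nv] <- subject$data[t, ]
  im <- RNifti::asNifti(arr)
  RNifti::sform(im) <- structure(g$affine, code = 2L)
  RNifti::qform(im) <- structure(g$affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Reconstruct a grid from a NIfTI header
#'
#' @param image An `niftiImage` or a path.
#' @param space_label Space tag for the grid.
#' @return A [volume_grid()].
#' @export
grid_from_nifti <- function(image, space_label = "MNI152") {
  if (is.character(image)) image <- RNifti::readNifti(image)
  aff <- unclass(RNifti::xform(image, useQuaternionFirst = FALSE))
  dm <- dim(image)[1:3]
  volume_grid(dm, matrix(as.numeric(aff), 4, 4), space_label)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI path.
#' @return A [brain_mask()] (nonzero voxels set).
#' @export
read_mask_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  g <- grid_from_nifti(im)
  brain_mask(g, array(as.array(im) != 0, g$shape))
}

#' Read a statistic volume from NIfTI
#'
#' @param path NIfTI path.
#' @param kind Statistic kind (`"r"`, `"z"`, `"t"`).
#' @param df Degrees of freedom for t maps.
#' @return A [stat_map()].
#' @export
read_stat_map_nifti <- function(path, kind = "z", df = NULL) {
  im <- RNifti::readNifti(path)
  g <- grid_from_nifti(im)
  stat_map(g, as.numeric(as.array(im)), kind = kind, df = df)
}

#' Read a 4D subject time series from NIfTI
#'
#' @param path NIfTI path of a 4D volume.
#' @param mask A [brain_mask()]; defaults to all voxels.
#' @param subject_id Identifier.
#' @return A [subject_time_series()].
#' @export
read_subject_nifti <- function(path, mask = NULL, subject_id = basename(path)) {
  im <- RNifti::readNifti(path)
  g <- grid_from_nifti(im)
  if (is.null(mask)) mask <- brain_mask(g, array(TRUE, g$shape))
  arr <- as.array(im)
  T <- dim(arr)[4]
  nv <- n_voxels(g)
  idx <- which(mask$voxels)
  data <- matrix(0, T, length(idx))
  for (t in seq_len(T)) data[t, ] <- arr[idx + (t - 1) * nv]
  subject_time_series(data, g, mask, subject_id)
}
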