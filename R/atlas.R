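#' Labeled volumetric parcellation atlas
#'
#' @param grid A [volume_grid()].
#' @param labels Integer array on the grid; 0 = background, regions 1..R.
#' @param centroids R x 3 matrix of region centroid world coordinates (mm).
#'   Computed from the label image when omitted.
#' @param hemisphere Character vector of length R with entries `"L"`/`"R"`.
#'   Inferred from the centroid x sign when omitted.
#' @param name Atlas name.
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(grid, labels, centroids = NULL, hemisphere = NULL,
                         name = "atlas") {
  labels <- array(as.integer(labels), grid$shape)
  R <- max(labels)
  if (R < 1L) stop("atlas has no regions")
  present <- tabulate(labels[labels > 0L], nbins = R)
  if (any(present == 0L))
    stop("atlas labels must cover 1..R; missing: ",
         paste(which(present == 0L), collapse = ","))
  if (is.null(centroids)) {
    ctr <- voxel_centers(grid)
    lab <- as.integer(labels)
    centroids <- do.call(rbind, lapply(seq_len(R), function(r)
      colMeans(ctr[lab == r, , drop = FALSE])))
  }
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == R, all(is.finite(centroids)))
  if (is.null(hemisphere)) hemisphere <- ifelse(centroids[, 1] < 0, "L", "R")
  stopifnot(length(hemisphere) == R, all(hemisphere %in% c("L", "R")))
  structure(list(grid = grid, labels = labels, centroids = centroids,
                 hemisphere = hemisphere, n_regions = R, name = name),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas '%s'> %d regions (%d L / %d R)\n", x$name,
              x$n_regions, sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  invisible(x)
}

#' Atlas-parcellated map values
#'
#' @param values Named numeric vector (names are not required); regional
#'   values.
#' @param regions Integer atlas label IDs the values correspond to.
#' @param name Map name.
#' @param atlas_name Name of the atlas the regions refer to.
#' @return An object of class `region_vector`.
#' @export
region_vector <- function(values, regions, name = "map", atlas_name = "atlas") {
  values <- as.numeric(values)
  regions <- as.integer(regions)
  stopifnot(length(values) == length(regions), !anyDuplicated(regions))
  structure(list(values = values, regions = regions, name = name,
                 atlas_name = atlas_name),
            class = "region_vector")
}

#' @export
print.region_vector <- function(x, ...) {
  cat(sprintf("<region_vector '%s'> %d regions, %d missing\n", x$name,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Downsample a voxel map to atlas regions
#'
#' Each region's value is the mean over its voxels of the input map
#' (statistic volume, overlap-count map, or binary mask). Regions with no
#' voxel on the grid are flagged missing (NA) with a warning. Optionally
#' restrict to one hemisphere's regions.
#'
#' @param map A [stat_map()], `overlap_map`, or [brain_mask()].
#' @param atlas A [region_atlas()] on the same grid.
#' @param hemisphere Optional `"L"` or `"R"` filter.
#' @return A [region_vector()].
#' @export
parcellate_map <- function(map, atlas, hemisphere = NULL) {
  vals <- if (inherits(map, "stat_map")) map$values
          else if (inherits(map, "overlap_map")) map$counts
          else if (inherits(map, "brain_mask")) map$voxels + 0
          else stop("unsupported map type")
  stop_if_grid_mismatch(map$grid, atlas$grid, "map and atlas")
  lab <- as.integer(atlas$labels)
  v <- as.numeric(vals)
  keep <- lab > 0L
  sums <- tapply(v[keep], lab[keep], mean)
  out <- rep(NA_real_, atlas$n_regions)
  out[as.integer(names(sums))] <- sums
  if (anyNA(out))
    warning(sum(is.na(out)), " region(s) have no voxels on the grid; flagged NA")
  regions <- seq_len(atlas$n_regions)
  if (!is.null(hemisphere)) {
    stopifnot(hemisphere %in% c("L", "R"))
    sel <- atlas$hemisphere == hemisphere
    out <- out[sel]
    regions <- regions[sel]
  }
  region_vector(out, regions,
                name = if (inherits(map, "stat_map")) map$kind else "map",
                atlas_name = atlas$name)
}

#' Paint regional values back onto the atlas grid
#'
#' @param rv A [region_vector()].
#' @param atlas The [region_atlas()] it refers to.
#' @param background Value for background voxels and regions absent from `rv`.
#' @return A numeric array on the atlas grid.
#' @export
volumize_region_vector <- function(rv, atlas, background = 0) {
  lut <- rep(background, atlas$n_regions + 1L)
  lut[rv$regions + 1L] <- rv$values
  array(lut[as.integer(atlas$labels) + 1L], atlas$grid$shape)
}

align_regions <- function(rv, regions) {
  idx <- match(regions, rv$regions)
  if (anyNA(idx)) stop("region vectors are not aligned: missing regions")
  rv$values[idx]
}
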