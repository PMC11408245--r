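#' Term association map set
#'
#' A set of meta-analytic term maps sharing one grid, for decoding a network
#' mask by spatial similarity.
#'
#' @param maps Named list of numeric arrays (one per term) on `grid`.
#' @param grid A [volume_grid()].
#' @param source Free-text provenance tag.
#' @return An object of class `term_map_set`.
#' @export
term_map_set <- function(maps, grid, source = "local") {
  if (is.null(names(maps)) || anyDuplicated(names(maps)))
    stop("term maps must have unique names")
  maps <- lapply(maps, function(m) {
    m <- as.numeric(m)
    stopifnot(length(m) == n_voxels(grid))
    dim(m) <- grid$shape
    m
  })
  structure(list(terms = names(maps), maps = maps, grid = grid, source = source),
            class = "term_map_set")
}

#' Decode a network mask against term maps
#'
#' Scores each term by the mean term-map value inside the mask, builds an
#' empirical null by permuting the mask's voxel labels within the permissible
#' support (whole grid by default, or a brain mask), and reports one-sided
#' permutation p-values with BH-FDR across terms, ranked by score (stable
#' ties).
#'
#' @param mask Non-empty [brain_mask()] (e.g. the 60 percent consensus).
#' @param terms A [term_map_set()] on the same grid.
#' @param n_perm Number of mask permutations.
#' @param rng_seed Integer seed.
#' @param within Optional [brain_mask()] restricting where permuted masks may
#'   fall.
#' @return Data frame (term, score, p, q, rank), sorted by rank.
#' @export
decode_terms <- function(mask, terms, n_perm = 1000, rng_seed = 1,
                         within = NULL) {
  stop_if_grid_mismatch(mask$grid, terms$grid, "mask and term maps")
  idx <- which(mask$voxels)
  if (!length(idx)) stop("decoding mask is empty")
  support <- if (is.null(within)) seq_len(n_voxels(mask$grid)) else {
    stop_if_grid_mismatch(mask$grid, within$grid, "mask and support")
    which(within$voxels)
  }
  V <- vapply(terms$maps, as.numeric, numeric(n_voxels(mask$grid)))
  obs <- colMeans(V[idx, , drop = FALSE])
  set.seed(rng_seed)
  exceed <- numeric(length(obs))
  for (p in seq_len(n_perm)) {
    pid <- sample(support, length(idx))
    exceed <- exceed + (colMeans(V[pid, , drop = FALSE]) >= obs)
  }
  pv <- (1 + exceed) / (1 + n_perm)
  qv <- stats::p.adjust(pv, method = "BH")
  ord <- order(-obs)  # stable for ties
  data.frame(term = terms$terms, score = obs, p = pv, q = qv,
             rank = match(seq_along(obs), ord),
             stringsAsFactors = FALSE)[ord, , drop = FALSE]
}
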