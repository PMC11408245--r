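#' Region x gene expression matrix
#'
#' @param values Regions x genes numeric matrix.
#' @param regions Integer atlas labels for the rows.
#' @param genes Character gene symbols for the columns (unique).
#' @param donor_id Optional donor identifier.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, regions, genes, donor_id = NULL) {
  values <- as.matrix(values)
  if (anyDuplicated(genes)) stop("duplicated gene symbols")
  if (nrow(values) < 2L) stop("need at least 2 regions")
  stopifnot(nrow(values) == length(regions), ncol(values) == length(genes))
  structure(list(values = values, regions = as.integer(regions),
                 genes = as.character(genes), donor_id = donor_id),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix%s> %d regions x %d genes\n",
              if (!is.null(x$donor_id)) paste0(" donor=", x$donor_id) else "",
              nrow(x$values), length(x$genes)))
  invisible(x)
}

#' Donor-similarity gene filter
#'
#' Scores each gene by the mean, over all donor pairs, of the Pearson
#' correlation between the two donors' regional expression profiles
#' (differential stability), keeps genes with mean similarity strictly above
#' `threshold`, and averages the retained genes across donors.
#'
#' @param per_donor List (>= 2) of [expression_matrix()] objects sharing the
#'   same region and gene index.
#' @param threshold Similarity threshold (strictly greater-than retains).
#' @return An [expression_matrix()] of donor-averaged retained genes, with a
#'   `similarity` attribute holding every gene's mean inter-donor similarity.
#' @export
filter_genes_by_donor_similarity <- function(per_donor, threshold = 0.1) {
  D <- length(per_donor)
  if (D < 2L) stop("need at least 2 donors")
  ref <- per_donor[[1]]
  for (m in per_donor) {
    if (!identical(m$genes, ref$genes) || !identical(m$regions, ref$regions))
      stop("donors must share region and gene indices")
  }
  zs <- lapply(per_donor, function(m) scale(m$values))  # R x G each
  R <- nrow(ref$values)
  pairs <- utils::combn(D, 2)
  sim <- rep(0, length(ref$genes))
  for (p in seq_len(ncol(pairs))) {
    a <- zs[[pairs[1, p]]]; b <- zs[[pairs[2, p]]]
    sim <- sim + colSums(a * b) / (R - 1)
  }
  sim <- sim / ncol(pairs)
  names(sim) <- ref$genes
  keep <- which(is.finite(sim) & sim > threshold)
  if (!length(keep)) stop("no genes pass the donor-similarity filter")
  avg <- Reduce(`+`, lapply(per_donor, function(m) m$values[, keep, drop = FALSE])) / D
  out <- expression_matrix(avg, ref$regions, ref$genes[keep], donor_id = "mean")
  attr(out, "similarity") <- sim
  out
}

#' First partial-least-squares component against a regional map
#'
#' Gene expression (predictors) and the regional map (univariate response)
#' are column z-scored; with a single response the first PLS component's gene
#' weights are exactly the normalized gene-response covariance vector
#' w = X'y / ||X'y||, which is the implementation used here. Region scores
#' are X w and explained variance is the squared correlation between scores
#' and the response.
#'
#' @param X An [expression_matrix()] (or plain matrix) of regions x genes.
#' @param y A [region_vector()] (or numeric vector) aligned with X's regions.
#' @return A `pls_result` with elements `weights` (named, unit length),
#'   `scores`, `var_explained`, and the aligned standardized inputs.
#' @export
pls1_fit <- function(X, y) {
  dat <- .align_xy(X, y)
  Xz <- .zscore_cols(dat$X)
  if (stats::sd(dat$y) == 0) stop("constant response map: PLS undefined")
  yz <- as.numeric(scale(dat$y))
  cvec <- as.numeric(crossprod(Xz, yz))
  nrm <- sqrt(sum(cvec^2))
  if (nrm == 0) stop("all predictors are orthogonal to the response")
  w <- cvec / nrm
  names(w) <- dat$genes
  scores <- as.numeric(Xz %*% w)
  ve <- suppressWarnings(stats::cor(scores, yz))^2
  if (!is.finite(ve)) ve <- 0
  structure(list(weights = w, scores = scores, var_explained = ve,
                 Xz = Xz, yz = yz, genes = dat$genes),
            class = "pls_result")
}

.align_xy <- function(X, y) {
  if (inherits(X, "expression_matrix")) {
    genes <- X$genes
    if (inherits(y, "region_vector")) yv <- align_regions(y, X$regions)
    else yv <- as.numeric(y)
    Xm <- X$values
  } else {
    Xm <- as.matrix(X)
    genes <- colnames(Xm) %||% paste0("g", seq_len(ncol(Xm)))
    yv <- if (inherits(y, "region_vector")) y$values else as.numeric(y)
  }
  if (length(yv) != nrow(Xm)) stop("X rows and y regions are not aligned")
  if (anyNA(Xm) || anyNA(yv)) stop("missing entries: filter before fitting")
  list(X = Xm, y = yv, genes = genes)
}

.zscore_cols <- function(m) {
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant columns carry no signal
  z[is.na(z)] <- 0
  z
}

#' Moran spectral randomization surrogates
#'
#' Generates spatial-null surrogates of a regional map that preserve its
#' spatial autocorrelation profile. A spatial weight matrix is built from
#' region centroids (inverse Euclidean distance, zero diagonal,
#' row-standardized then symmetrized), the map is decomposed on the
#' orthonormal eigenbasis of the doubly centered weight matrix (Moran
#' eigenvectors), and each surrogate redraws the coefficients with random
#' signs (singleton procedure), preserving the squared-coefficient spectral
#' profile and hence Moran's I. Each surrogate is then exactly rescaled to
#' the observed mean and variance.
#'
#' @param y A [region_vector()] or numeric vector.
#' @param atlas A [region_atlas()] (centroids of `y`'s regions are used), or
#'   an n x 3 centroid matrix.
#' @param n_surrogates Number of surrogates.
#' @param rng_seed Integer seed.
#' @param weights `"invdist"` (default) or `"knn"`.
#' @param k Neighbour count for `weights = "knn"`.
#' @return List of numeric surrogate vectors (empty when `n_surrogates = 0`).
#' @export
msr_surrogates <- function(y, atlas, n_surrogates = 1000, rng_seed = 1,
                           weights = c("invdist", "knn"), k = 8) {
  weights <- match.arg(weights)
  yv <- if (inherits(y, "region_vector")) y$values else as.numeric(y)
  ctr <- .centroids_for(y, atlas)
  if (n_surrogates == 0) return(list())
  E <- .moran_eigenbasis(ctr, weights, k)
  n <- length(yv)
  mu <- mean(yv); s <- stats::sd(yv)
  cf <- as.numeric(crossprod(E, yv - mu))
  set.seed(rng_seed)
  lapply(seq_len(n_surrogates), function(i) {
    flips <- sample(c(-1, 1), length(cf), replace = TRUE)
    srr <- as.numeric(E %*% (flips * cf))
    # enforce the observed first two moments exactly
    srr <- srr - mean(srr)
    ssd <- stats::sd(srr)
    if (ssd > 0) srr <- srr * (s / ssd)
    srr + mu
  })
}

.centroids_for <- function(y, atlas) {
  if (inherits(atlas, "region_atlas")) {
    regions <- if (inherits(y, "region_vector")) y$regions
               else seq_len(atlas$n_regions)
    atlas$centroids[regions, , drop = FALSE]
  } else as.matrix(atlas)
}

.moran_weight_matrix <- function(ctr, weights = "invdist", k = 8) {
  d <- as.matrix(stats::dist(ctr))
  if (any(d[upper.tri(d)] == 0))
    stop("degenerate atlas: coincident region centroids")
  if (weights == "invdist") {
    W <- 1 / d
    diag(W) <- 0
  } else {
    n <- nrow(d)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
  }
  W <- W / rowSums(W)
  (W + t(W)) / 2
}

.moran_eigenbasis <- function(ctr, weights = "invdist", k = 8) {
  W <- .moran_weight_matrix(ctr, weights, k)
  n <- nrow(W)
  H <- diag(n) - matrix(1 / n, n, n)
  eigen(H %*% W %*% H, symmetric = TRUE)$vectors
}

#' Moran's I spatial autocorrelation
#'
#' @param y Numeric vector or [region_vector()].
#' @param atlas A [region_atlas()] or centroid matrix.
#' @inheritParams msr_surrogates
#' @return Moran's I (scalar).
#' @export
moran_i <- function(y, atlas, weights = c("invdist", "knn"), k = 8) {
  weights <- match.arg(weights)
  yv <- if (inherits(y, "region_vector")) y$values else as.numeric(y)
  W <- .moran_weight_matrix(.centroids_for(y, atlas), weights, k)
  n <- length(yv)
  yc <- yv - mean(yv)
  (n / sum(W)) * as.numeric(t(yc) %*% W %*% yc) / sum(yc^2)
}

#' One-sided spatial permutation p-value
#'
#' p = (1 + #\{surrogate >= observed\}) / (1 + n_surrogates); ties count
#' against the observation.
#'
#' @param observed Observed statistic (e.g. PLS1 variance explained).
#' @param surrogate_stats Numeric vector of the statistic under surrogates.
#' @return p-value in (0, 1].
#' @export
spatial_p_value <- function(observed, surrogate_stats) {
  if (length(surrogate_stats) < 1L) stop("need at least one surrogate")
  (1 + sum(surrogate_stats >= observed)) / (1 + length(surrogate_stats))
}

#' Bootstrap z-scores for PLS1 gene weights
#'
#' Resamples regions with replacement, refits the first PLS component on the
#' restandardized resample, aligns each bootstrap component's sign to the
#' original by the correlation of its scores with the response, and returns
#' z_g = original weight_g / bootstrap SD of weight_g. Genes whose bootstrap
#' SD is zero get +/-Inf and are flagged via the `n_degenerate` attribute.
#'
#' Weights are taken on the per-gene correlation scale (the component
#' direction, before unit-norm scaling): with a univariate response the
#' weight is proportional to the gene-response correlation, and dividing by
#' the global norm would couple every gene's bootstrap spread to the whole
#' gene set's (under a null the resampled norm grows by about sqrt(2),
#' deflating every SD and inflating every z by the same factor). On the
#' correlation scale the ratio is calibrated: null genes give approximately
#' standard-normal z.
#'
#' @inheritParams pls1_fit
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param rng_seed Integer seed.
#' @return Named numeric vector of per-gene z-scores.
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 5000, rng_seed = 1) {
  if (n_boot < 2L) stop("need at least 2 bootstrap resamples")
  dat <- .align_xy(X, y)
  R <- nrow(dat$X)
  G <- length(dat$genes)
  boot_w <- function(Xm, yv) {
    Xz <- .zscore_cols(Xm)
    yz <- as.numeric(scale(yv))
    w <- as.numeric(crossprod(Xz, yz)) / (length(yv) - 1)  # per-gene correlation
    if (sum(as.numeric(Xz %*% w) * yz) < 0) w <- -w  # sign-align to response
    w
  }
  if (stats::sd(dat$y) == 0) stop("constant response map")
  w0 <- boot_w(dat$X, dat$y)
  set.seed(rng_seed)
  wmat <- matrix(NA_real_, n_boot, G)
  n_resampled <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(R, R, replace = TRUE)
      if (stats::sd(dat$y[idx]) > 0) break
      n_resampled <- n_resampled + 1L
    }
    wmat[b, ] <- boot_w(dat$X[idx, , drop = FALSE], dat$y[idx])
  }
  if (n_resampled > 0)
    message(n_resampled, " degenerate bootstrap draw(s) with constant response resampled")
  sds <- apply(wmat, 2, stats::sd)
  z <- ifelse(sds > 0, w0 / sds, ifelse(w0 == 0, 0, sign(w0) * Inf))
  names(z) <- dat$genes
  attr(z, "n_degenerate") <- sum(sds == 0)
  z
}

#' Select genes by bootstrap z threshold
#'
#' Splits genes into a positively and a negatively weighted set at
#' `|z| > z_thresh` (the conventional cut 3.69 corresponds to a two-sided
#' normal tail of about 2e-4). Two-sided normal p-values and BH q-values are
#' reported alongside. Non-finite z entries are excluded from the sets.
#'
#' @param z Named per-gene z vector, e.g. from [bootstrap_gene_z()].
#' @param z_thresh Threshold (default 3.69).
#' @return List with `positive`, `negative` (character vectors) and `table`
#'   (gene, z, p, q).
#' @export
select_genes <- function(z, z_thresh = 3.69) {
  ok <- is.finite(z)
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(z))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(
    positive = names(z)[ok & z > z_thresh],
    negative = names(z)[ok & z < -z_thresh],
    table = data.frame(gene = names(z), z = as.numeric(z), p = p, q = q,
                       stringsAsFactors = FALSE)
  )
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure; q-values are the monotone-adjusted p * m / rank.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q Target FDR level.
#' @return List with `reject` (logical) and `qvalues`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(reject = qv <= q, qvalues = qv)
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' drawing at least the observed overlap between the gene set and the term's
#' genes (both restricted to the background), with BH q-values across terms.
#'
#' @param gene_set Character vector of selected genes (must be a subset of
#'   `background`).
#' @param annotations Named list mapping term -> character vector of genes.
#' @param background Character vector of background genes.
#' @return Data frame (term, n_term, overlap, p, q), sorted by p.
#' @export
hypergeom_ora <- function(gene_set, annotations, background) {
  if (length(background) == 0L) stop("empty background")
  background <- unique(background)
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of the background")
  gene_set <- unique(gene_set)
  N <- length(background); n <- length(gene_set)
  rows <- lapply(names(annotations), function(term) {
    tg <- intersect(unique(annotations[[term]]), background)
    K <- length(tg)
    ov <- length(intersect(gene_set, tg))
    p <- if (K == 0L) 1 else stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n_term = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
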