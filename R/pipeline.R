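#' Run configuration
#'
#' Assembles input paths and analysis parameters with the canonical defaults
#' (4 mm seed radius, t > 3 binarization, 60 percent overlap, |z| > 3.69 gene
#' cut, 5000 surrogates and bootstraps, left hemisphere for transcriptomics).
#' Can be read from a YAML file with the same field names.
#'
#' @param coordinates Path to the coordinate table TSV (required).
#' @param connectome_manifest TSV with columns `subject_id`, `path` listing
#'   4D NIfTI subjects (required).
#' @param brain_mask Optional NIfTI brain mask path.
#' @param atlas Optional atlas NIfTI path (labels 1..R).
#' @param expression Optional directory of per-donor expression TSVs.
#' @param tracers Optional tracer manifest TSV (`receptor`, `system`,
#'   `cohort_n`, `path`).
#' @param term_maps Optional directory of term-map NIfTI files.
#' @param radius,t_thresh,fraction,z_thresh,n_surr,n_boot,hemisphere,seed
#'   Analysis parameters.
#' @param loeo,sweep Whether to run leave-one-experiment-out and the
#'   robustness sweep.
#' @return An object of class `run_config`.
#' @export
run_config <- function(coordinates, connectome_manifest, brain_mask = NULL,
                       atlas = NULL, expression = NULL, tracers = NULL,
                       term_maps = NULL, radius = 4, t_thresh = 3,
                       fraction = 0.6, z_thresh = 3.69, n_surr = 5000,
                       n_boot = 5000, hemisphere = "L", seed = 1,
                       loeo = TRUE, sweep = FALSE) {
  cfg <- as.list(environment())
  stopifnot(radius >= 0, fraction > 0, fraction <= 1, n_surr >= 1,
            n_boot >= 2, hemisphere %in% c("L", "R", "both"))
  for (f in c("coordinates", "connectome_manifest", "brain_mask", "atlas",
              "expression", "tracers", "term_maps")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path does not exist: ", f, " = ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments; relative
#'   paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("coordinates", "connectome_manifest", "brain_mask", "atlas",
              "expression", "tracers", "term_maps")) {
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  }
  do.call(run_config, y)
}

.write_sidecar <- function(path, ...) {
  jsonlite::write_json(list(...), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.stage_log <- function(stage, t0, note = "") {
  message(sprintf("[%s] %s done in %.1fs %s", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0, note))
}

#' Run the full activation-network-mapping pipeline
#'
#' Executes, in order: seed construction from the coordinate table,
#' experiment-level t-maps against the connectome, overlap consensus (plus
#' leave-one-experiment-out and an optional parameter sweep), and - when the
#' corresponding inputs are configured - transcriptomic decoding (donor
#' filter, PLS1, spatial null, bootstrap gene z), receptor-system
#' relative-importance regression, and term decoding. Every stage writes its
#' outputs plus a JSON parameter sidecar under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  # --- coordinates -> combined seeds
  t0 <- as.numeric(Sys.time())
  coords <- read_coordinate_table(config$coordinates)
  records <- as_experiment_records(coords)
  manifest <- utils::read.table(config$connectome_manifest, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  grid <- grid_from_nifti(manifest$path[1])
  bmask <- if (!is.null(config$brain_mask)) read_mask_nifti(config$brain_mask)
           else brain_mask(grid, array(TRUE, grid$shape))
  seeds <- lapply(records, combine_experiment_seed, radius = config$radius,
                  grid = grid)
  seed_dir <- file.path(out_dir, "seeds")
  dir.create(seed_dir, showWarnings = FALSE)
  for (k in names(seeds))
    write_volume_nifti(seeds[[k]], file.path(seed_dir, paste0(gsub("[^A-Za-z0-9]", "_", k), ".nii.gz")))
  .write_sidecar(file.path(seed_dir, "seeds"), radius = config$radius,
                 n_experiments = length(seeds))
  .stage_log("seeds", t0, sprintf("(%d experiments)", length(seeds)))
  res$seeds <- seeds

  # --- connectome -> experiment t-maps (subjects streamed from disk)
  t0 <- as.numeric(Sys.time())
  loader <- function(i) read_subject_nifti(manifest$path[i], bmask,
                                           manifest$subject_id[i])
  tmaps <- compute_experiment_tmaps(loader, seeds, n_subjects = nrow(manifest))
  tmap_dir <- file.path(out_dir, "tmaps")
  dir.create(tmap_dir, showWarnings = FALSE)
  for (k in names(tmaps))
    write_volume_nifti(tmaps[[k]], file.path(tmap_dir, paste0(gsub("[^A-Za-z0-9]", "_", k), "_t.nii.gz")))
  .write_sidecar(file.path(tmap_dir, "tmaps"), n_subjects = nrow(manifest),
                 df = nrow(manifest) - 1, t_thresh = config$t_thresh)
  .stage_log("tmaps", t0, sprintf("(%d subjects)", nrow(manifest)))
  res$tmaps <- tmaps

  # --- overlap consensus + robustness
  t0 <- as.numeric(Sys.time())
  binmaps <- lapply(tmaps, threshold_binarize, t_thresh = config$t_thresh)
  ov <- overlap_counts(binmaps)
  consensus <- consensus_mask(ov, config$fraction)
  ov_dir <- file.path(out_dir, "overlap")
  dir.create(ov_dir, showWarnings = FALSE)
  write_volume_nifti(stat_map(grid, ov$counts, kind = "z"),
                     file.path(ov_dir, "overlap_counts.nii.gz"))
  write_volume_nifti(consensus, file.path(ov_dir, "consensus.nii.gz"))
  if (config$loeo) {
    loeo <- leave_one_experiment_out(binmaps, config$fraction)
    utils::write.table(loeo, file.path(ov_dir, "loeo_dice.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$loeo <- loeo
  }
  .write_sidecar(file.path(ov_dir, "consensus.nii.gz"), fraction = config$fraction,
                 n_experiments = ov$n_experiments,
                 min_count = ceiling(config$fraction * ov$n_experiments - 1e-9),
                 n_voxels = mask_size(consensus))
  .stage_log("overlap", t0, sprintf("(consensus %d voxels)", mask_size(consensus)))
  res$overlap <- ov
  res$consensus <- consensus

  atlas <- if (!is.null(config$atlas)) {
    im <- RNifti::readNifti(config$atlas)
    region_atlas(grid_from_nifti(im), as.array(im), name = basename(config$atlas))
  } else NULL

  # --- transcriptomics
  if (!is.null(config$expression) && !is.null(atlas)) {
    t0 <- as.numeric(Sys.time())
    donor_files <- sort(list.files(config$expression, pattern = "\\.tsv$",
                                   full.names = TRUE))
    donors <- lapply(donor_files, read_expression_tsv)
    expr <- filter_genes_by_donor_similarity(donors, threshold = 0.1)
    hemi <- if (config$hemisphere == "both") NULL else config$hemisphere
    y <- parcellate_map(ov, atlas, hemisphere = hemi)
    keep <- match(y$regions, expr$regions)
    if (anyNA(keep)) stop("expression matrix misses atlas regions")
    exprh <- expression_matrix(expr$values[keep, , drop = FALSE], y$regions,
                               expr$genes)
    fit <- pls1_fit(exprh, y)
    surr <- msr_surrogates(y, atlas, n_surrogates = config$n_surr,
                           rng_seed = config$seed + 1L)
    surr_ve <- vapply(surr, function(s) pls1_fit(exprh, s)$var_explained,
                      numeric(1))
    p_moran <- spatial_p_value(fit$var_explained, surr_ve)
    z <- bootstrap_gene_z(exprh, y, n_boot = config$n_boot,
                          rng_seed = config$seed + 2L)
    sel <- select_genes(z, z_thresh = config$z_thresh)
    gene_dir <- file.path(out_dir, "genes")
    dir.create(gene_dir, showWarnings = FALSE)
    utils::write.table(sel$table[order(-sel$table$z), ],
                       file.path(gene_dir, "gene_z.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    .write_sidecar(file.path(gene_dir, "pls1"),
                   var_explained = fit$var_explained, p_moran = p_moran,
                   n_genes = length(fit$weights),
                   n_positive = length(sel$positive),
                   n_negative = length(sel$negative),
                   n_surr = config$n_surr, n_boot = config$n_boot,
                   z_thresh = config$z_thresh, seed = config$seed)
    .stage_log("transcriptomics", t0,
               sprintf("(PLS1 %.1f%%, p = %.3g)", 100 * fit$var_explained, p_moran))
    res$pls <- fit; res$p_moran <- p_moran; res$gene_selection <- sel
  }

  # --- receptors
  if (!is.null(config$tracers) && !is.null(atlas)) {
    t0 <- as.numeric(Sys.time())
    tman <- utils::read.table(config$tracers, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    tmaps_r <- lapply(seq_len(nrow(tman)), function(i) {
      im <- RNifti::readNifti(tman$path[i])
      tracer_map(as.numeric(as.array(im)), grid_from_nifti(im),
                 tman$receptor[i], tman$system[i], tman$cohort_n[i])
    })
    systems <- build_system_maps(tmaps_r, atlas)
    ov_regions <- parcellate_map(ov, atlas)
    rec <- bootstrap_relative_importance(ov_regions, systems,
                                         n_boot = max(100, config$n_boot),
                                         rng_seed = config$seed + 3L)
    rec_dir <- file.path(out_dir, "receptors")
    dir.create(rec_dir, showWarnings = FALSE)
    utils::write.table(rec, file.path(rec_dir, "relative_importance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fullfit <- fit_receptor_model(ov_regions, systems)
    .write_sidecar(file.path(rec_dir, "model"), adj_r2 = fullfit$adj_r2,
                   f = fullfit$f_stat, seed = config$seed)
    .stage_log("receptors", t0, sprintf("(adj R2 = %.2f)", fullfit$adj_r2))
    res$receptors <- rec
  }

  # --- term decoding
  if (!is.null(config$term_maps)) {
    t0 <- as.numeric(Sys.time())
    files <- sort(list.files(config$term_maps, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    tm <- lapply(files, function(f) as.array(RNifti::readNifti(f)))
    names(tm) <- sub("\\.nii(\\.gz)?$", "", basename(files))
    tms <- term_map_set(tm, grid, source = config$term_maps)
    terms <- decode_terms(consensus, tms, n_perm = min(2000, config$n_surr),
                          rng_seed = config$seed + 4L, within = bmask)
    term_dir <- file.path(out_dir, "terms")
    dir.create(term_dir, showWarnings = FALSE)
    utils::write.table(terms, file.path(term_dir, "term_decoding.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    .stage_log("terms", t0)
    res$terms <- terms
  }

  invisible(res)
}

#' Read an expression matrix TSV
#'
#' Rows are regions (first column `region`, integer atlas label), remaining
#' columns genes.
#'
#' @param path TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  expression_matrix(as.matrix(df[, -1, drop = FALSE]), df$region,
                    colnames(df)[-1],
                    donor_id = sub("\\.tsv$", "", basename(path)))
}

#' Write scenario inputs to disk
#'
#' Materializes a synthetic scenario as the on-disk input tree [run_all()]
#' consumes: coordinate table, 4D subject NIfTIs plus manifest, atlas, brain
#' mask, per-donor expression TSVs, tracer NIfTIs plus manifest, and a JSON
#' scenario echo.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario_inputs <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- scenario_grid(scenario)
  atlas <- make_toy_atlas(scenario, grid)
  net <- planted_network(scenario, grid)

  write_coordinate_table(simulate_coordinate_table(scenario, grid),
                         file.path(dir, "coordinates.tsv"))
  write_volume_nifti(net, file.path(dir, "planted_network.nii.gz"))
  write_volume_nifti(brain_mask(grid, array(TRUE, grid$shape)),
                     file.path(dir, "brain_mask.nii.gz"))
  write_volume_nifti(atlas, file.path(dir, "atlas.nii.gz"))

  subj_dir <- file.path(dir, "connectome")
  dir.create(subj_dir, showWarnings = FALSE)
  paths <- character(scenario$n_subjects)
  for (i in seq_len(scenario$n_subjects)) {
    paths[i] <- file.path(subj_dir, sprintf("sub%04d.nii.gz", i))
    write_subject_nifti(simulate_subject(scenario, i, grid), paths[i])
  }
  utils::write.table(data.frame(subject_id = sprintf("sub%04d", seq_along(paths)),
                                path = paths),
                     file.path(dir, "connectome_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  target <- parcellate_map(net, atlas)
  expr_dir <- file.path(dir, "expression")
  dir.create(expr_dir, showWarnings = FALSE)
  donors <- simulate_expression(scenario, target, atlas)
  for (d in donors) {
    df <- data.frame(region = d$regions, d$values, check.names = FALSE)
    colnames(df) <- c("region", d$genes)
    utils::write.table(df, file.path(expr_dir, paste0(d$donor_id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  tr_dir <- file.path(dir, "tracers")
  dir.create(tr_dir, showWarnings = FALSE)
  tr <- simulate_receptor_maps(scenario, target, atlas)
  tpaths <- data.frame(receptor = character(0), system = character(0),
                       cohort_n = numeric(0), path = character(0))
  for (i in seq_along(tr)) {
    p <- file.path(tr_dir, sprintf("tracer%02d.nii.gz", i))
    write_volume_nifti(tr[[i]]$values, p, grid = grid)
    tpaths[i, ] <- list(tr[[i]]$receptor, tr[[i]]$system, tr[[i]]$cohort_n, p)
  }
  utils::write.table(tpaths, file.path(dir, "tracer_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  sc <- scenario
  class(sc) <- NULL
  jsonlite::write_json(sc, file.path(dir, "scenario.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
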