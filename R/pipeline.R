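#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one list, with the
#' package defaults. Any element can be overridden; `sim` is a list of
#' overrides passed to [sim_config()] and `ihc` a list passed to
#' [simulate_ihc_cells()].
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer master seed (the IHC table uses `seed + 1`).
#' @param stages Character vector of stages to run, in fixed order.
#' @param k Negative-probe filter SD multiplier.
#' @param window,clip CNV smoothing parameters.
#' @param gain_thresh,loss_thresh Hallmark call thresholds.
#' @param z_nonmalig_thresh,z_malig_thresh,tam_z_thresh Purity-filter
#'   thresholds.
#' @param sim,ihc Named lists of generator overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("geomxpure_run_"),
                            seed = 1,
                            stages = c("simulate", "preprocess", "cnv",
                                       "filter", "score", "compare", "ihc"),
                            k = 2, window = 101, clip = 3,
                            gain_thresh = 0.15, loss_thresh = -0.15,
                            z_nonmalig_thresh = 1.0, z_malig_thresh = 0.0,
                            tam_z_thresh = 0.0,
                            sim = list(), ihc = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_paths <- function(dir) {
  list(counts = file.path(dir, "counts.tsv"),
       negprobes = file.path(dir, "negprobes.tsv"),
       meta = file.path(dir, "aoi_meta.tsv"),
       annotation = file.path(dir, "gene_annotation.tsv"),
       gmt = file.path(dir, "signatures.gmt"),
       truth_aoi = file.path(dir, "truth_aoi.tsv"),
       truth_gene = file.path(dir, "truth_gene.tsv"),
       roles = file.path(dir, "signature_roles.tsv"),
       gene_filter = file.path(dir, "gene_filter.tsv"),
       normalized = file.path(dir, "normalized.tsv"),
       cnv_calls = file.path(dir, "cnv_calls.tsv"),
       scores_sox2 = file.path(dir, "scores_sox2.tsv"),
       scores_iba1 = file.path(dir, "scores_iba1.tsv"),
       purity_calls = file.path(dir, "purity_calls.tsv"),
       iba1_calls = file.path(dir, "iba1_calls.tsv"),
       excluded_tumors = file.path(dir, "excluded_tumors.tsv"),
       scores_tumor = file.path(dir, "scores_tumor.tsv"),
       de_results = file.path(dir, "de_results.tsv"),
       lmm_contrasts = file.path(dir, "lmm_contrasts.tsv"),
       ihc_cells = file.path(dir, "ihc_cells.tsv"),
       ihc_truth = file.path(dir, "ihc_truth.tsv"),
       ihc_positivity = file.path(dir, "ihc_positivity.tsv"),
       ihc_tests = file.path(dir, "ihc_tests.tsv"),
       manifest = file.path(dir, "manifest.json"))
}

require_inputs <- function(paths, stage, needed, produced_by) {
  missing <- needed[!file.exists(unlist(paths[needed]))]
  if (length(missing) > 0) {
    stop("stage '", stage, "' is missing input(s) ",
         paste(missing, collapse = ", "),
         "; run stage '", produced_by, "' first")
  }
}

#' Run the purity-aware GeoMx analysis pipeline
#'
#' Executes the workflow simulate -> preprocess -> cnv -> filter -> score
#' -> compare -> ihc with plain-file handoff between stages: every stage
#' reads the previous stage's on-disk outputs from `config$out_dir` and
#' writes its own, so each intermediate is auditable. A manifest with an
#' MD5 content hash per artifact is written at the end.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, the manifest as a tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- stage_paths(dir)
  order <- c("simulate", "preprocess", "cnv", "filter", "score", "compare", "ihc")
  stages <- order[order %in% config$stages]

  for (st in stages) {
    message("[geomxpure] stage: ", st)
    switch(st,
           simulate = stage_simulate(config, paths),
           preprocess = stage_preprocess(config, paths),
           cnv = stage_cnv(config, paths),
           filter = stage_filter(config, paths),
           score = stage_score(config, paths),
           compare = stage_compare(config, paths),
           ihc = stage_ihc(config, paths))
  }

  files <- list.files(dir, full.names = TRUE)
  files <- setdiff(files, paths$manifest)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(list(seed = config$seed, files = manifest),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, paths) {
  sim_args <- utils::modifyList(config$sim, list(seed = config$seed))
  sim <- simulate_cohort(do.call(sim_config, sim_args))
  write_cohort(sim, dirname(paths$counts))
  readr::write_tsv(tibble::tibble(signature = names(sim$signatures$roles),
                                  role = unname(sim$signatures$roles)),
                   paths$roles)
  ihc_args <- utils::modifyList(config$ihc, list(seed = config$seed + 1))
  ihc <- do.call(simulate_ihc_cells, ihc_args)
  readr::write_tsv(ihc$cells, paths$ihc_cells)
  readr::write_tsv(ihc$truth, paths$ihc_truth)
  invisible(NULL)
}

read_stage_dataset <- function(paths, stage, produced_by = "simulate") {
  require_inputs(paths, stage, c("counts", "negprobes", "meta"), produced_by)
  read_dataset(paths$counts, paths$negprobes, paths$meta)
}

read_stage_norm <- function(paths, stage) {
  require_inputs(paths, stage, "normalized", "preprocess")
  m <- read_count_table_numeric(paths$normalized)
  normalized_matrix(m, normalized = TRUE, batch_corrected = TRUE)
}

read_count_table_numeric <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

read_stage_signatures <- function(paths, stage) {
  require_inputs(paths, stage, c("gmt", "roles"), "simulate")
  roles_tab <- readr::read_tsv(paths$roles, show_col_types = FALSE)
  roles <- stats::setNames(roles_tab$role, roles_tab$signature)
  read_gmt(paths$gmt, roles = roles)
}

stage_preprocess <- function(config, paths) {
  ds <- read_stage_dataset(paths, "preprocess")
  pre <- preprocess_dataset(ds, k = config$k)
  readr::write_tsv(pre$gene_filter, paths$gene_filter)
  readr::write_tsv(tibble::as_tibble(unclass(pre$norm), rownames = "gene_id"),
                   paths$normalized)
  invisible(NULL)
}

stage_cnv <- function(config, paths) {
  ds <- read_stage_dataset(paths, "cnv")
  norm <- read_stage_norm(paths, "cnv")
  require_inputs(paths, "cnv", "annotation", "simulate")
  chrom_order <- unique(readr::read_tsv(paths$annotation,
                                        show_col_types = FALSE)$chrom)
  ann <- read_gene_annotation(paths$annotation, chrom_order = chrom_order)
  ref <- ds$aoi_meta$aoi_id[ds$aoi_meta$segment == "IBA1"]
  qry <- ds$aoi_meta$aoi_id[ds$aoi_meta$segment == "SOX2"]
  prof <- compute_cnv_profile(norm, ann, reference_aois = ref,
                              query_aois = qry, window = config$window,
                              clip = config$clip)
  calls <- score_and_call(prof, gain_thresh = config$gain_thresh,
                          loss_thresh = config$loss_thresh)
  readr::write_tsv(calls, paths$cnv_calls)
  invisible(NULL)
}

stage_filter <- function(config, paths) {
  ds <- read_stage_dataset(paths, "filter")
  norm <- read_stage_norm(paths, "filter")
  sigs <- read_stage_signatures(paths, "filter")
  require_inputs(paths, "filter", "cnv_calls", "cnv")
  calls <- readr::read_tsv(paths$cnv_calls, show_col_types = FALSE)

  sox2 <- ds$aoi_meta$aoi_id[ds$aoi_meta$segment == "SOX2"]
  iba1 <- ds$aoi_meta$aoi_id[ds$aoi_meta$segment == "IBA1"]
  sc_sox2 <- aggregate_zscore(norm, sigs, population = sox2)
  sc_iba1 <- aggregate_zscore(norm, sigs, population = iba1)
  readr::write_tsv(sc_sox2, paths$scores_sox2)
  readr::write_tsv(sc_iba1, paths$scores_iba1)

  purity <- classify_sox2_aois(calls, sc_sox2,
                               z_nonmalig_thresh = config$z_nonmalig_thresh,
                               z_malig_thresh = config$z_malig_thresh)
  readr::write_tsv(purity, paths$purity_calls)
  iba1_calls <- filter_iba1_aois(sc_iba1, tam_z_thresh = config$tam_z_thresh)
  readr::write_tsv(iba1_calls, paths$iba1_calls)
  rep <- exclusion_report(purity, ds$aoi_meta)
  readr::write_tsv(rep$tumors, paths$excluded_tumors)
  invisible(NULL)
}

stage_score <- function(config, paths) {
  ds <- read_stage_dataset(paths, "score")
  require_inputs(paths, "score", c("scores_sox2", "purity_calls"), "filter")
  sc <- readr::read_tsv(paths$scores_sox2, show_col_types = FALSE)
  purity <- readr::read_tsv(paths$purity_calls, show_col_types = FALSE)
  keep <- purity$aoi_id[purity$decision == "keep"]
  tum <- aggregate_by_tumor(sc, ds$aoi_meta, keep_aois = keep)
  readr::write_tsv(tum, paths$scores_tumor)
  invisible(NULL)
}

stage_compare <- function(config, paths) {
  ds <- read_stage_dataset(paths, "compare")
  require_inputs(paths, "compare", c("purity_calls", "scores_sox2"), "filter")
  purity <- readr::read_tsv(paths$purity_calls, show_col_types = FALSE)
  keep <- purity$aoi_id[purity$decision == "keep"]

  ## pseudobulk DE: treated vs control recurrences, surviving SOX2+ AOIs
  rec_aois <- ds$aoi_meta$aoi_id[ds$aoi_meta$setting == "recurrent"]
  pb <- pseudobulk(ds, keep_aois = intersect(keep, rec_aois), segment = "SOX2")
  de <- nb_wald_de(pb$counts, pb$tumors$arm)
  readr::write_tsv(de$table, paths$de_results)

  ## mixed model on the strongest malignant-state score per AOI
  sc <- readr::read_tsv(paths$scores_sox2, show_col_types = FALSE)
  resp <- sc[sc$role == "malignant_state" & sc$aoi_id %in% keep, ] |>
    dplyr::group_by(.data$aoi_id) |>
    dplyr::summarise(y = max(.data$score), .groups = "drop") |>
    dplyr::left_join(ds$aoi_meta[, c("aoi_id", "patient_id", "arm", "setting")],
                     by = "aoi_id") |>
    dplyr::mutate(group = paste(.data$arm, .data$setting, sep = "_"))
  fit <- fit_random_intercept(resp, response = "y", group = "group",
                              patient = "patient_id")
  emm <- emmeans_tukey(fit)
  readr::write_tsv(emm$contrasts, paths$lmm_contrasts)
  invisible(NULL)
}

stage_ihc <- function(config, paths) {
  require_inputs(paths, "ihc", c("ihc_cells", "ihc_truth"), "simulate")
  cells <- readr::read_tsv(paths$ihc_cells, show_col_types = FALSE)
  truth <- readr::read_tsv(paths$ihc_truth, show_col_types = FALSE)
  res <- percent_positive(classify_cells(cells))
  readr::write_tsv(dplyr::left_join(res$tumor, truth, by = "tumor_id"),
                   paths$ihc_positivity)
  tests <- compare_groups(res, truth)
  readr::write_tsv(tests, paths$ihc_tests)
  invisible(NULL)
}
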