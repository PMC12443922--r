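#' Configuration for the synthetic GeoMx cohort generator
#'
#' Defines a GeoMx-like glioblastoma cohort with known ground truth. The
#' defaults emulate a recurrence cohort profiled in SOX2+ (tumor cell) and
#' IBA1+ (macrophage/microglia) segments: 30 patients, most with a matched
#' primary tumor, two thirds treated at recurrence, two experimental
#' batches, and the hallmark broad alterations (chromosome 7 gain,
#' chromosome 10 loss) present in most tumors' malignant cells. Counts are
#' negative-binomial around a library-size scaled, purity-weighted mixture
#' of cell-type expression programs; negative probes share the background
#' mean of unexpressed genes.
#'
#' @param n_patients Number of patients; every patient has a recurrent tumor.
#' @param paired_fraction Fraction of patients that also contribute a
#'   matched primary tumor.
#' @param treated_fraction Fraction of patients whose recurrence is
#'   immunotherapy-treated (`arm = "treated"`).
#' @param n_genes,n_negprobes Panel sizes.
#' @param aois_per_tumor ROIs per tumor; each ROI yields one SOX2+ and one
#'   IBA1+ AOI.
#' @param purity_grid Malignant fractions assignable to SOX2+ AOIs
#'   (uniformly sampled per AOI). Must be non-empty, values in \[0, 1\].
#' @param cnv_dosage Named multiplicative dosage on malignant-program
#'   expression for all genes on the affected chromosome:
#'   `c(chr7 = ..., chr10 = ...)`, gain > 1, loss < 1. A dosage of exactly 1
#'   means the alteration is absent.
#' @param batch_effects List with numeric `location` (per-batch mean log2
#'   shift of gene means) and `scale` (per-batch multiplier on the NB
#'   dispersion); their common length sets the number of batches.
#' @param batch_gene_sd SD of the gene-wise log2 batch offsets around each
#'   batch's location.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param libsize_mean,libsize_lognormal_sigma AOI library sizes are
#'   `libsize_mean * exp(rnorm(0, sigma))`.
#' @param signature_module_sizes Named integer vector: genes per planted
#'   signature module. Names containing "oligodendrocyte" or "tam" are
#'   tagged non-malignant, "interferon"/"cell_cycle"/"myeloid" get their
#'   matching role, all others are malignant states.
#' @param module_log2fc Log2 elevation of a module's genes in the cell type
#'   expressing it, over the shared baseline; default 3 (8-fold), the
#'   enrichment scale of cell-type marker panels.
#' @param expressed_fraction Fraction of genes expressed above background;
#'   the rest sit at the negative-probe background level.
#' @param n_chromosomes Genes are spread evenly over `chr1..chrN`; must be
#'   at least 10 so chr7 and chr10 exist.
#' @param cnv_window Smallest smoothing window the annotation must support;
#'   configs whose chromosomes hold fewer genes are rejected.
#' @param cnv_positive_fraction Fraction of patients whose malignant cells
#'   carry the hallmark alterations.
#' @param de_log2fc,n_de_genes Planted treatment effect: `n_de_genes`
#'   expressed genes shifted by `de_log2fc` log2 units in treated recurrent
#'   tumors. Default 0 (null scenario).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 30,
                       paired_fraction = 0.9,
                       treated_fraction = 2 / 3,
                       n_genes = 3000,
                       n_negprobes = 100,
                       aois_per_tumor = 3,
                       purity_grid = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
                       cnv_dosage = c(chr7 = 1.5, chr10 = 0.5),
                       batch_effects = list(location = c(0, 0.5),
                                            scale = c(1, 1.5)),
                       batch_gene_sd = 0.2,
                       nb_dispersion = 0.1,
                       libsize_mean = 3e5,
                       libsize_lognormal_sigma = 0.4,
                       signature_module_sizes = c(MES = 40, NPC = 40, AC = 40,
                                                  oligodendrocyte = 40,
                                                  tam = 40, interferon = 30,
                                                  cell_cycle = 30,
                                                  myeloid = 30),
                       module_log2fc = 3,
                       expressed_fraction = 0.85,
                       n_chromosomes = 10,
                       cnv_window = 101,
                       cnv_positive_fraction = 0.9,
                       de_log2fc = 0,
                       n_de_genes = 0,
                       seed = 1) {
  cfg <- as.list(environment())

  fracs <- c(paired_fraction, treated_fraction, expressed_fraction,
             cnv_positive_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must be in [0, 1]")
  if (length(purity_grid) == 0) stop("purity_grid must be non-empty")
  if (any(purity_grid < 0 | purity_grid > 1)) stop("purity values must be in [0, 1]")
  if (any(cnv_dosage <= 0)) stop("cnv_dosage values must be > 0")
  if (!all(c("chr7", "chr10") %in% names(cnv_dosage))) {
    stop("cnv_dosage must name chr7 and chr10")
  }
  if (n_genes < sum(signature_module_sizes)) {
    stop("n_genes must be at least the sum of signature module sizes")
  }
  if (is.null(names(signature_module_sizes))) {
    stop("signature_module_sizes must be named")
  }
  if (length(batch_effects$location) != length(batch_effects$scale)) {
    stop("batch_effects location and scale must have equal length")
  }
  if (n_chromosomes < 10) stop("need at least 10 chromosomes so chr7/chr10 exist")
  if (floor(n_genes / n_chromosomes) < cnv_window) {
    stop("each chromosome would hold fewer genes (",
         floor(n_genes / n_chromosomes),
         ") than the CNV smoothing window (", cnv_window, ")")
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

module_role <- function(nm) {
  if (grepl("oligodendrocyte|tam", nm, ignore.case = TRUE)) return("non_malignant")
  if (grepl("interferon", nm, ignore.case = TRUE)) return("interferon")
  if (grepl("cell_cycle", nm, ignore.case = TRUE)) return("cell_cycle")
  if (grepl("myeloid", nm, ignore.case = TRUE)) return("myeloid")
  "malignant_state"
}

#' Simulate a GeoMx-like AOI cohort with known ground truth
#'
#' Generates an [aoi_dataset()], its gene annotation, the planted
#' [signature_set()] and a ground-truth record. Expression of every AOI is
#' a purity-weighted mixture of three cell-type programs (malignant, with a
#' per-tumor malignant state; oligodendrocyte; TAM), each a log2 elevation
#' of its planted gene module over a shared baseline. CNV dosage acts on
#' all genes of chr7/chr10 in the malignant program of hallmark-positive
#' tumors. SOX2+ AOIs draw their malignant fraction from the purity grid;
#' IBA1+ AOIs are a TAM-dominated non-malignant mixture.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` ([aoi_dataset()]), `annotation`
#'   (gene annotation tibble), `signatures` ([signature_set()]), `truth`
#'   (list of tibbles `aoi` and `gene`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  cfg <- config

  ## genes and genome layout
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_of <- sample(rep_len(chroms, cfg$n_genes))
  ann <- dplyr::bind_rows(lapply(chroms, function(ch) {
    g <- gene_ids[chrom_of == ch]
    tibble::tibble(gene_id = g, chrom = ch,
                   start = seq_along(g) * 100000L)
  }))
  ann <- gene_annotation(ann, chrom_order = chroms)

  ## expressed genes, baseline weights, module membership
  expressed <- rep(FALSE, cfg$n_genes)
  expressed[sample.int(cfg$n_genes, round(cfg$expressed_fraction * cfg$n_genes))] <- TRUE
  bg_log2 <- 1
  base_log2 <- rep(bg_log2, cfg$n_genes)
  base_log2[expressed] <- stats::rnorm(sum(expressed), mean = 5, sd = 1.5)

  mod_names <- names(cfg$signature_module_sizes)
  pool <- sample(which(expressed))
  module_of <- rep(NA_character_, cfg$n_genes)
  ofs <- 0
  sets <- list()
  for (nm in mod_names) {
    sz <- cfg$signature_module_sizes[[nm]]
    idx <- pool[(ofs + 1):(ofs + sz)]
    module_of[idx] <- nm
    sets[[nm]] <- gene_ids[sort(idx)]
    ofs <- ofs + sz
  }
  roles <- vapply(mod_names, module_role, character(1))
  sigs <- signature_set(sets, roles = roles)

  mal_states <- mod_names[roles == "malignant_state"]
  if (length(mal_states) == 0) stop("at least one malignant-state module required")

  ## program weight vectors (linear scale)
  elev <- function(modules, lfc) {
    x <- base_log2
    for (i in seq_along(modules)) {
      x[which(module_of == modules[i])] <- x[which(module_of == modules[i])] + lfc[i]
    }
    2^x
  }
  has <- function(nm) nm %in% mod_names
  w_oligo <- elev("oligodendrocyte"[has("oligodendrocyte")], cfg$module_log2fc)
  tam_mods <- c("tam"[has("tam")], "interferon"[has("interferon")],
                "myeloid"[has("myeloid")])
  w_tam <- elev(tam_mods, c(cfg$module_log2fc, 1, 1)[seq_along(tam_mods)])

  ## patients and tumors
  pid <- sprintf("P%02d", seq_len(cfg$n_patients))
  treated <- rep(FALSE, cfg$n_patients)
  treated[sample.int(cfg$n_patients, round(cfg$treated_fraction * cfg$n_patients))] <- TRUE
  paired <- rep(FALSE, cfg$n_patients)
  paired[sample.int(cfg$n_patients, round(cfg$paired_fraction * cfg$n_patients))] <- TRUE
  cnv_pos <- stats::runif(cfg$n_patients) < cfg$cnv_positive_fraction

  tumors <- dplyr::bind_rows(lapply(seq_len(cfg$n_patients), function(i) {
    settings <- if (paired[i]) c("primary", "recurrent") else "recurrent"
    tibble::tibble(patient_id = pid[i],
                   setting = settings,
                   arm = ifelse(treated[i], "treated", "control"),
                   cnv_positive = cnv_pos[i],
                   tumor_id = paste(pid[i], settings, sep = "_"))
  }))
  tumors$mal_state <- sample(mal_states, nrow(tumors), replace = TRUE)

  ## batches: alternate tumors within arm x setting strata (balanced)
  n_batch <- length(cfg$batch_effects$location)
  tumors <- tumors |>
    dplyr::group_by(.data$arm, .data$setting) |>
    dplyr::mutate(batch = paste0("batch", ((dplyr::row_number() - 1) %% n_batch) + 1)) |>
    dplyr::ungroup()

  ## planted treatment effect
  true_lfc <- rep(0, cfg$n_genes)
  if (cfg$n_de_genes > 0 && cfg$de_log2fc != 0) {
    de_idx <- sample(which(expressed & is.na(module_of)), cfg$n_de_genes)
    true_lfc[de_idx] <- cfg$de_log2fc
  }

  ## per-tumor malignant program (CNV dosage on all chr7/chr10 genes)
  dos7 <- cfg$cnv_dosage[["chr7"]]
  dos10 <- cfg$cnv_dosage[["chr10"]]
  w_mal_for <- function(state, cnv_positive) {
    cc <- "cell_cycle"[has("cell_cycle")]
    w <- elev(c(state, cc), c(cfg$module_log2fc, 1)[seq_len(1 + length(cc))])
    if (cnv_positive) {
      w[ann_chrom == "chr7"] <- w[ann_chrom == "chr7"] * dos7
      w[ann_chrom == "chr10"] <- w[ann_chrom == "chr10"] * dos10
    }
    w
  }
  ann_chrom <- chrom_of  # gene order of the counts matrix

  ## AOIs: each ROI yields a SOX2+ and an IBA1+ segment
  meta_rows <- list()
  weight_cols <- list()
  truth_rows <- list()
  gamma <- matrix(stats::rnorm(cfg$n_genes * n_batch,
                               mean = rep(cfg$batch_effects$location, each = cfg$n_genes),
                               sd = cfg$batch_gene_sd),
                  nrow = cfg$n_genes)
  gamma_np <- matrix(stats::rnorm(cfg$n_negprobes * n_batch,
                                  mean = rep(cfg$batch_effects$location, each = cfg$n_negprobes),
                                  sd = cfg$batch_gene_sd),
                     nrow = cfg$n_negprobes)
  w_bg <- 2^bg_log2

  for (t in seq_len(nrow(tumors))) {
    tm <- tumors[t, ]
    w_mal <- w_mal_for(tm$mal_state, tm$cnv_positive)
    treated_rec <- tm$arm == "treated" && tm$setting == "recurrent"
    for (r in seq_len(cfg$aois_per_tumor)) {
      roi <- sprintf("%s_R%02d", tm$tumor_id, r)
      core <- sprintf("%s_C%02d", tm$tumor_id, ceiling(r / 2))
      for (seg in c("SOX2", "IBA1")) {
        p <- if (seg == "SOX2") {
          cfg$purity_grid[sample.int(length(cfg$purity_grid), 1)]
        } else 0
        w <- if (seg == "SOX2") {
          p * w_mal + (1 - p) * (0.7 * w_oligo + 0.3 * w_tam)
        } else {
          0.15 * w_oligo + 0.85 * w_tam
        }
        if (treated_rec) w <- w * 2^true_lfc
        aoi <- paste(roi, seg, sep = "_")
        meta_rows[[aoi]] <- tibble::tibble(
          aoi_id = aoi, roi_id = roi, core_id = core,
          tumor_id = tm$tumor_id, patient_id = tm$patient_id,
          setting = tm$setting, arm = tm$arm, segment = seg,
          batch = tm$batch)
        weight_cols[[aoi]] <- w
        truth_rows[[aoi]] <- tibble::tibble(
          aoi_id = aoi, tumor_id = tm$tumor_id, segment = seg,
          malignant_fraction = p,
          chr7_gain = tm$cnv_positive && p > 0 && dos7 > 1,
          chr10_loss = tm$cnv_positive && p > 0 && dos10 < 1,
          batch = tm$batch)
      }
    }
  }
  meta <- dplyr::bind_rows(meta_rows)
  truth_aoi <- dplyr::bind_rows(truth_rows)
  W <- do.call(cbind, weight_cols)

  ## counts
  n_aoi <- nrow(meta)
  lib <- cfg$libsize_mean * exp(stats::rnorm(n_aoi, 0, cfg$libsize_lognormal_sigma))
  batch_idx <- as.integer(sub("batch", "", meta$batch))
  denom <- colSums(W) + cfg$n_negprobes * w_bg
  counts <- matrix(0L, cfg$n_genes, n_aoi,
                   dimnames = list(gene_ids, meta$aoi_id))
  npc <- matrix(0L, cfg$n_negprobes, n_aoi,
                dimnames = list(sprintf("NegProbe%03d", seq_len(cfg$n_negprobes)),
                                meta$aoi_id))
  for (i in seq_len(n_aoi)) {
    b <- batch_idx[i]
    mu <- lib[i] * W[, i] / denom[i] * 2^gamma[, b]
    mu_np <- lib[i] * w_bg / denom[i] * 2^gamma_np[, b]
    disp <- cfg$nb_dispersion * cfg$batch_effects$scale[b]
    if (disp == 0) {
      counts[, i] <- stats::rpois(cfg$n_genes, mu)
      npc[, i] <- stats::rpois(cfg$n_negprobes, mu_np)
    } else {
      counts[, i] <- stats::rnbinom(cfg$n_genes, mu = mu, size = 1 / disp)
      npc[, i] <- stats::rnbinom(cfg$n_negprobes, mu = mu_np, size = 1 / disp)
    }
  }

  truth_gene <- tibble::tibble(gene_id = gene_ids,
                               chrom = chrom_of,
                               expressed = expressed,
                               module = module_of,
                               true_log2fc = true_lfc)

  list(dataset = aoi_dataset(counts, npc, meta),
       annotation = ann,
       signatures = sigs,
       truth = list(aoi = truth_aoi, gene = truth_gene),
       config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Writes the same formats [read_dataset()], [read_gene_annotation()] and
#' [read_gmt()] consume, plus ground-truth TSVs.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dataset(sim$dataset, dir)
  write_gene_annotation(sim$annotation, file.path(dir, "gene_annotation.tsv"))
  write_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  readr::write_tsv(sim$truth$aoi, file.path(dir, "truth_aoi.tsv"))
  readr::write_tsv(sim$truth$gene, file.path(dir, "truth_gene.tsv"))
  invisible(dir)
}

#' Simulate per-cell IHC feature tables
#'
#' Emulates the per-cell export of a chromogenic DAB stain quantification:
#' each cell has a mean DAB optical density drawn from a two-component
#' log-normal mixture (negative cells centred well below the 0.3 OD
#' threshold, positive cells above it) and a cell area drawn so that a
#' small fraction falls under the 20 um^2 inclusion limit. Per-tumor true
#' positive fractions are recorded; recurrences are shifted by `effect`.
#'
#' @param n_tumors_per_arm Patients per arm.
#' @param pairs If `TRUE` every patient contributes a primary and a
#'   recurrent tumor.
#' @param effect Additive shift in true positive fraction of recurrent vs
#'   primary tumors.
#' @param baseline_positive True positive fraction in primary tumors.
#' @param n_cells_per_roi,rois_per_tumor Sampling depth.
#' @param od_neg_meanlog,od_pos_meanlog,od_sdlog Log-normal OD components.
#' @param area_meanlog,area_sdlog Log-normal cell areas (um^2).
#' @param seed Integer seed.
#' @return List with `cells` (tibble: cell_id, roi_id, tumor_id,
#'   dab_od_mean, area_um2) and `truth` (tibble: tumor_id, patient_id,
#'   setting, arm, true_positive_fraction).
#' @export
simulate_ihc_cells <- function(n_tumors_per_arm = 10,
                               pairs = TRUE,
                               effect = 0.02,
                               baseline_positive = 0.01,
                               n_cells_per_roi = 500,
                               rois_per_tumor = 3,
                               od_neg_meanlog = log(0.08),
                               od_pos_meanlog = log(0.6),
                               od_sdlog = 0.25,
                               area_meanlog = log(40),
                               area_sdlog = 0.5,
                               seed = 1) {
  stopifnot(n_tumors_per_arm >= 1, n_cells_per_roi >= 1)
  withr::local_seed(seed)

  design <- tidyr::expand_grid(arm = c("treated", "control"),
                               idx = seq_len(n_tumors_per_arm))
  design$patient_id <- sprintf("%s_P%02d", substr(design$arm, 1, 1), design$idx)
  settings <- if (pairs) c("primary", "recurrent") else "recurrent"
  tumors <- tidyr::expand_grid(design, setting = settings)
  tumors$tumor_id <- paste(tumors$patient_id, tumors$setting, sep = "_")
  tumors$true_positive_fraction <- pmin(1, pmax(0,
    baseline_positive + ifelse(tumors$setting == "recurrent", effect, 0)))

  cells <- dplyr::bind_rows(lapply(seq_len(nrow(tumors)), function(t) {
    tm <- tumors[t, ]
    dplyr::bind_rows(lapply(seq_len(rois_per_tumor), function(r) {
      n <- n_cells_per_roi
      pos <- stats::runif(n) < tm$true_positive_fraction
      od <- exp(stats::rnorm(n,
                             mean = ifelse(pos, od_pos_meanlog, od_neg_meanlog),
                             sd = od_sdlog))
      tibble::tibble(
        cell_id = sprintf("%s_R%02d_c%04d", tm$tumor_id, r, seq_len(n)),
        roi_id = sprintf("%s_R%02d", tm$tumor_id, r),
        tumor_id = tm$tumor_id,
        dab_od_mean = od,
        area_um2 = exp(stats::rnorm(n, area_meanlog, area_sdlog)))
    }))
  }))

  list(cells = cells,
       truth = tumors[, c("tumor_id", "patient_id", "setting", "arm",
                          "true_positive_fraction")])
}
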