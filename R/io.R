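#' Read an AOI dataset from disk
#'
#' Reads the three on-disk artifacts that define an [aoi_dataset()]: a
#' genes x AOIs counts table, a negative-probe counts table, and the per-AOI
#' annotation table. Count tables are TSV with the gene/probe id in the
#' first column and one column per AOI; annotations are TSV with one row
#' per AOI. A counts path ending in `.mtx` is read as MatrixMarket with
#' `<path>.rownames` / `<path>.colnames` sidecar files.
#'
#' @param counts_path,negprobe_path,meta_path File paths.
#' @return An [aoi_dataset()].
#' @export
read_dataset <- function(counts_path, negprobe_path, meta_path) {
  counts <- read_count_table(counts_path)
  negprobes <- read_count_table(negprobe_path)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  aoi_dataset(counts, negprobes, meta)
}

#' Write an AOI dataset to disk
#'
#' Inverse of [read_dataset()]; writes `counts.tsv`, `negprobes.tsv` and
#' `aoi_meta.tsv` into `dir`.
#'
#' @param x An [aoi_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "aoi_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             negprobes = file.path(dir, "negprobes.tsv"),
             meta = file.path(dir, "aoi_meta.tsv"))
  write_count_table(x$counts, paths[["counts"]], id_col = "gene_id")
  write_count_table(x$negprobe_counts, paths[["negprobes"]], id_col = "probe_id")
  readr::write_tsv(x$aoi_meta, paths[["meta"]])
  invisible(paths)
}

read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

write_count_table <- function(m, path, id_col = "gene_id") {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
    return(invisible(path))
  }
  tab <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Gene-set signatures with role tags
#'
#' A `signature_set` maps signature names to gene lists, with a role tag per
#' signature distinguishing malignant cell states from non-malignant cell
#' types and functional programs.
#'
#' @param sets Named list of character vectors (gene ids).
#' @param roles Named character vector mapping signature name to one of
#'   `"malignant_state"`, `"non_malignant"`, `"cell_cycle"`, `"interferon"`,
#'   `"myeloid"`. Signatures without a supplied role default to
#'   `"malignant_state"`.
#' @return A `signature_set` object.
#' @export
signature_set <- function(sets, roles = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("signatures must have unique names")
  }
  valid_roles <- c("malignant_state", "non_malignant", "cell_cycle",
                   "interferon", "myeloid")
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) stop("empty gene list for signature: ",
                              paste(empty, collapse = ", "))
  sets <- lapply(sets, as.character)
  role_vec <- rep("malignant_state", length(sets))
  names(role_vec) <- names(sets)
  if (!is.null(roles)) {
    bad <- setdiff(roles, valid_roles)
    if (length(bad) > 0) stop("unknown role(s): ", paste(bad, collapse = ", "))
    role_vec[names(roles)] <- roles
  }
  structure(list(sets = sets, roles = role_vec), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", length(x$sets), " signatures\n", sep = "")
  for (nm in names(x$sets)) {
    cat("  ", nm, " [", x$roles[[nm]], "]: ", length(x$sets[[nm]]), " genes\n",
        sep = "")
  }
  invisible(x)
}

#' Read gene-set signatures from a GMT file
#'
#' Standard GMT dialect (`name TAB description TAB gene TAB gene ...`).
#' Duplicate genes within a set are removed with a warning; empty sets are
#' an error. Role tags are supplied separately since GMT carries none.
#'
#' @param path GMT file path.
#' @param roles Optional named character vector of role tags, see
#'   [signature_set()].
#' @return A [signature_set()].
#' @export
read_gmt <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  n_dup <- vapply(sets, function(g) sum(duplicated(g)), integer(1))
  if (any(n_dup > 0)) {
    warning("duplicate genes removed in signature(s): ",
            paste(names(sets)[n_dup > 0], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  signature_set(sets, roles = roles)
}

#' Write a signature set as GMT
#' @param x A [signature_set()].
#' @param path Output path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "signature_set"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$roles[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `chrom`, `start`, `gene_id` (header required,
#' extra columns ignored). Returns one row per gene with a genome ordering
#' index: chromosomes in the order given by `chrom_order`, genes within a
#' chromosome by start position. Positions are 1-based and used only for
#' ordering. Chromosome order is explicit to avoid lexicographic
#' chr10 < chr2 mistakes.
#'
#' @param path File path.
#' @param chrom_order Character vector giving chromosome order; defaults to
#'   chr1..chr22, chrX, chrY.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `genome_order`.
#' @export
read_gene_annotation <- function(path, chrom_order = default_chrom_order()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("chrom", "start", "gene_id")
  if (!all(needed %in% names(tab))) {
    stop("annotation must have columns: ", paste(needed, collapse = ", "))
  }
  gene_annotation(tab[, needed], chrom_order = chrom_order)
}

#' Build a validated gene annotation from a data frame
#' @param tab Data frame with `gene_id`, `chrom`, `start`.
#' @inheritParams read_gene_annotation
#' @return Tibble with a `genome_order` column.
#' @export
gene_annotation <- function(tab, chrom_order = default_chrom_order()) {
  tab <- tibble::as_tibble(tab)
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  unknown <- setdiff(unique(tab$chrom), chrom_order)
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from chrom_order: ", paste(unknown, collapse = ", "))
  }
  tab$chrom <- factor(tab$chrom, levels = chrom_order)
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  tab$chrom <- as.character(tab$chrom)
  tab$genome_order <- seq_len(nrow(tab))
  tab
}

#' @rdname read_gene_annotation
#' @export
default_chrom_order <- function() paste0("chr", c(1:22, "X", "Y"))

#' Write a gene annotation table
#' @param ann Annotation tibble as returned by [gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(ann, path) {
  readr::write_tsv(ann[, c("chrom", "start", "gene_id")], path)
  invisible(path)
}
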