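#' AOI-level GeoMx dataset
#'
#' The central container for segmented GeoMx data: a genes x AOIs count
#' matrix, a negative-probe x AOIs count matrix, and per-AOI annotations.
#' Columns of both matrices and rows of `aoi_meta` are kept in the same
#' AOI order, which every downstream function relies on.
#'
#' @param counts Integer matrix, genes x AOIs, with rownames (gene ids) and
#'   colnames (AOI ids).
#' @param negprobe_counts Integer matrix, negative probes x AOIs, colnames
#'   matching `counts`.
#' @param aoi_meta Data frame with one row per AOI. Required columns:
#'   `aoi_id`, `roi_id`, `core_id`, `tumor_id`, `patient_id`,
#'   `setting` ("primary"/"recurrent"), `arm` ("treated"/"control"),
#'   `segment` ("SOX2"/"IBA1"), `batch`.
#'
#' @return An object of class `aoi_dataset`: a list with elements `counts`,
#'   `negprobe_counts`, `aoi_meta` (tibble) and `gene_ids`.
#' @export
aoi_dataset <- function(counts, negprobe_counts, aoi_meta) {
  counts <- as.matrix(counts)
  negprobe_counts <- as.matrix(negprobe_counts)
  aoi_meta <- tibble::as_tibble(aoi_meta)

  required <- c("aoi_id", "roi_id", "core_id", "tumor_id", "patient_id",
                "setting", "arm", "segment", "batch")
  missing_cols <- setdiff(required, names(aoi_meta))
  if (length(missing_cols) > 0) {
    stop("aoi_meta is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and AOI ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in counts: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(aoi_meta$aoi_id)) stop("aoi_id values must be unique")

  check_counts <- function(m, what) {
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
      stop(what, " must be non-negative integers")
    }
  }
  check_counts(counts, "counts")
  check_counts(negprobe_counts, "negprobe_counts")

  ids_counts <- colnames(counts)
  mism <- c(setdiff(ids_counts, aoi_meta$aoi_id), setdiff(aoi_meta$aoi_id, ids_counts))
  if (length(mism) > 0) {
    stop("AOI ids disagree between counts and aoi_meta: ",
         paste(unique(mism), collapse = ", "))
  }
  mism_np <- c(setdiff(ids_counts, colnames(negprobe_counts)),
               setdiff(colnames(negprobe_counts), ids_counts))
  if (length(mism_np) > 0) {
    stop("AOI ids disagree between counts and negprobe_counts: ",
         paste(unique(mism_np), collapse = ", "))
  }

  # one tumor -> one (patient, setting)
  tum <- unique(aoi_meta[, c("tumor_id", "patient_id", "setting")])
  if (anyDuplicated(tum$tumor_id)) {
    stop("a tumor_id maps to more than one (patient_id, setting)")
  }

  aoi_meta <- aoi_meta[match(ids_counts, aoi_meta$aoi_id), , drop = FALSE]
  negprobe_counts <- negprobe_counts[, ids_counts, drop = FALSE]

  structure(
    list(counts = counts,
         negprobe_counts = negprobe_counts,
         aoi_meta = aoi_meta,
         gene_ids = rownames(counts)),
    class = "aoi_dataset"
  )
}

#' @export
print.aoi_dataset <- function(x, ...) {
  cat("<aoi_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts), " AOIs; ",
      nrow(x$negprobe_counts), " negative probes\n", sep = "")
  cat("  segments: ", paste(names(table(x$aoi_meta$segment)),
                            table(x$aoi_meta$segment), collapse = ", "), "\n", sep = "")
  cat("  tumors: ", length(unique(x$aoi_meta$tumor_id)),
      "; patients: ", length(unique(x$aoi_meta$patient_id)),
      "; batches: ", length(unique(x$aoi_meta$batch)), "\n", sep = "")
  invisible(x)
}

#' Number of AOIs / genes in an `aoi_dataset`
#' @param x An `aoi_dataset`.
#' @export
n_aois <- function(x) ncol(x$counts)

#' @rdname n_aois
#' @export
n_genes <- function(x) nrow(x$counts)
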