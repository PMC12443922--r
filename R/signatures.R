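#' Aggregated signature Z-scores
#'
#' Centered-and-scaled scoring of gene-set signatures: within the scored
#' AOI population each gene is Z-transformed (mean 0, SD 1 across AOIs),
#' and a signature's score per AOI is the mean Z over the signature genes
#' present in the matrix. Scores are therefore relative to the chosen
#' population — score within the population you intend to compare.
#'
#' @param norm Normalized log2 expression matrix (genes x AOIs).
#' @param sigs A [signature_set()].
#' @param population Optional character vector of AOI ids defining the
#'   scored population (default: all columns). At least 2 AOIs.
#' @return Long tibble: `aoi_id`, `signature`, `role`, `score`.
#' @export
aggregate_zscore <- function(norm, sigs, population = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  m <- unclass(norm)
  if (!is.null(population)) {
    missing <- setdiff(population, colnames(m))
    if (length(missing) > 0) stop("population AOIs absent from matrix: ",
                                  paste(utils::head(missing, 5), collapse = ", "))
    m <- m[, population, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 AOIs to compute population Z-scores")

  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) contribute 0 to scores")
  }
  z <- (m - mu) / ifelse(zero_var, 1, sdv)
  z[zero_var, ] <- 0

  purrr::imap_dfr(sigs$sets, function(genes, nm) {
    present <- intersect(genes, rownames(m))
    if (length(present) == 0) {
      stop("no genes of signature '", nm, "' present in the matrix")
    }
    if (length(present) < 0.5 * length(genes)) {
      warning("fewer than half the genes of signature '", nm,
              "' are present (", length(present), "/", length(genes), ")")
    }
    tibble::tibble(aoi_id = colnames(m),
                   signature = nm,
                   role = unname(sigs$roles[[nm]]),
                   score = unname(colMeans(z[present, , drop = FALSE])))
  })
}

#' Aggregate AOI-level signature scores to tumor level
#'
#' Per tumor (and signature), the unweighted mean over its surviving AOIs.
#' Tumors with no surviving AOI are absent from the output.
#'
#' @param scores Long score tibble from [aggregate_zscore()].
#' @param aoi_meta AOI metadata (columns `aoi_id`, `tumor_id`, ...).
#' @param keep_aois Optional character vector restricting to surviving
#'   AOIs (e.g. from the purity filter).
#' @return Tibble: `tumor_id`, `signature`, `role`, `score`, `n_aois`.
#' @export
aggregate_by_tumor <- function(scores, aoi_meta, keep_aois = NULL) {
  if (!is.null(keep_aois)) scores <- scores[scores$aoi_id %in% keep_aois, ]
  unmapped <- setdiff(scores$aoi_id, aoi_meta$aoi_id)
  if (length(unmapped) > 0) stop("scored AOIs missing from metadata: ",
                                 paste(utils::head(unmapped, 5), collapse = ", "))
  scores |>
    dplyr::left_join(aoi_meta[, c("aoi_id", "tumor_id")], by = "aoi_id") |>
    dplyr::group_by(.data$tumor_id, .data$signature, .data$role) |>
    dplyr::summarise(score = mean(.data$score), n_aois = dplyr::n(),
                     .groups = "drop")
}
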