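#' Infer broad copy-number profiles from expression
#'
#' Expression-based CNV inference in the style of reference-cell methods:
#' per gene, the log-ratio of a query AOI's log2 expression to the mean
#' log2 expression of a reference AOI set (by default the IBA1+
#' macrophage/microglia compartment, the available non-malignant
#' reference); ratios are clipped, median-centered per AOI, smoothed by a
#' centered moving average along genome order within each chromosome
#' (window truncated at chromosome edges, so no cross-chromosome bleed),
#' and re-centered after smoothing. Median centering precedes clipping so
#' profiles are invariant to constant shifts of a query AOI. Broad events such as whole-chromosome
#' gains and losses survive the smoothing; gene-level programs do not.
#'
#' @param norm Normalized log2 expression matrix (genes x AOIs), e.g. from
#'   [quantile_normalize()] / [correct_batch()].
#' @param annotation Gene annotation tibble from [gene_annotation()];
#'   genes absent from it are excluded from CNV analysis only.
#' @param reference_aois Character vector of reference AOI ids (non-empty).
#' @param query_aois AOIs to profile; default all columns not in the
#'   reference.
#' @param window Odd moving-average window in genes (default 101); must not
#'   exceed the smallest analyzed chromosome.
#' @param clip Log-ratios are clipped to +/- `clip` before smoothing.
#' @return A `cnv_profile`: list with `smoothed` (genome-ordered genes x
#'   query AOIs matrix), `genes` (annotation rows used), `window`, `clip`,
#'   `reference_aois`.
#' @export
compute_cnv_profile <- function(norm, annotation, reference_aois,
                                query_aois = NULL, window = 101, clip = 3) {
  m <- unclass(norm)
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  if (length(reference_aois) == 0) stop("reference_aois must be non-empty")
  missing_ref <- setdiff(reference_aois, colnames(m))
  if (length(missing_ref) > 0) stop("reference AOIs absent from matrix: ",
                                    paste(utils::head(missing_ref, 5), collapse = ", "))
  if (is.null(query_aois)) query_aois <- setdiff(colnames(m), reference_aois)

  ann <- annotation[annotation$gene_id %in% rownames(m), , drop = FALSE]
  ann <- ann[order(ann$genome_order), , drop = FALSE]

  ## drop chromosomes too small to smooth meaningfully
  sizes <- table(ann$chrom)
  tiny <- names(sizes)[sizes < 3]
  if (length(tiny) > 0) {
    warning("chromosome(s) with < 3 genes excluded from CNV analysis: ",
            paste(tiny, collapse = ", "))
    ann <- ann[!ann$chrom %in% tiny, , drop = FALSE]
  }
  if (any(table(ann$chrom) < window)) {
    stop("window (", window, ") exceeds the smallest analyzed chromosome (",
         min(table(ann$chrom)), " genes)")
  }

  ref_mean <- rowMeans(m[ann$gene_id, reference_aois, drop = FALSE])
  lr <- m[ann$gene_id, query_aois, drop = FALSE] - ref_mean
  ## center each AOI by its genome-wide median first, so the profile is
  ## invariant to constant shifts of the query AOI, then clip
  lr <- sweep(lr, 2, apply(lr, 2, stats::median))
  lr <- pmin(pmax(lr, -clip), clip)

  chrom_f <- factor(ann$chrom, levels = unique(ann$chrom))
  smoothed <- lr
  for (ch in levels(chrom_f)) {
    idx <- which(chrom_f == ch)
    smoothed[idx, ] <- apply(lr[idx, , drop = FALSE], 2, running_mean,
                             window = window)
  }
  smoothed <- sweep(smoothed, 2, apply(smoothed, 2, stats::median))

  structure(list(smoothed = smoothed, genes = ann, window = window,
                 clip = clip, reference_aois = reference_aois),
            class = "cnv_profile")
}

## centered moving average with window truncated at the edges
running_mean <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("<cnv_profile> ", nrow(x$smoothed), " genes x ", ncol(x$smoothed),
      " AOIs; window = ", x$window, ", clip = ", x$clip,
      ", reference n = ", length(x$reference_aois), "\n", sep = "")
  invisible(x)
}

#' Score chromosomes and call hallmark alterations
#'
#' Per-AOI, per-chromosome score = mean smoothed log-ratio over the
#' chromosome's genes. Hallmark calls use strict thresholds: chr7 gain when
#' the chr7 score exceeds `gain_thresh`, chr10 loss when the chr10 score
#' falls below `loss_thresh`. A 2-group Ward hierarchical clustering on the
#' (chr7, chr10) score pair is returned alongside as the supervised
#' grouping aid; it never overrides the threshold calls.
#'
#' @param profile A `cnv_profile` from [compute_cnv_profile()].
#' @param gain_thresh,loss_thresh Call thresholds (log2 scale), with
#'   `gain_thresh > 0 > loss_thresh`.
#' @param gain_chrom,loss_chrom Chromosome labels scored for gain and loss.
#' @return Tibble with one row per AOI: `aoi_id`, `score_chr7`,
#'   `score_chr10`, `chr7_gain`, `chr10_loss`, `cluster`. Full
#'   per-chromosome scores attached as attribute `chrom_scores` (long
#'   tibble).
#' @export
score_and_call <- function(profile, gain_thresh = 0.15, loss_thresh = -0.15,
                           gain_chrom = "chr7", loss_chrom = "chr10") {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!(gain_thresh > 0 && loss_thresh < 0)) {
    stop("need gain_thresh > 0 > loss_thresh")
  }
  chrom_f <- factor(profile$genes$chrom, levels = unique(profile$genes$chrom))
  # AOIs x chromosomes matrix of mean smoothed log-ratios
  score_mat <- vapply(levels(chrom_f), function(ch) {
    colMeans(profile$smoothed[chrom_f == ch, , drop = FALSE])
  }, numeric(ncol(profile$smoothed)))
  for (ch in c(gain_chrom, loss_chrom)) {
    if (!ch %in% colnames(score_mat)) stop("chromosome absent from profile: ", ch)
  }
  s7 <- score_mat[, gain_chrom]
  s10 <- score_mat[, loss_chrom]

  two <- cbind(s7, s10)
  if (nrow(two) >= 2 && stats::sd(as.vector(two)) > 0 &&
      nrow(unique(round(two, 12))) >= 2) {
    hc <- stats::hclust(stats::dist(two), method = "ward.D2")
    cluster <- stats::cutree(hc, k = 2)
  } else {
    warning("degenerate chromosome scores; returning a single cluster")
    cluster <- rep(1L, nrow(two))
  }

  calls <- tibble::tibble(
    aoi_id = colnames(profile$smoothed),
    score_chr7 = unname(s7),
    score_chr10 = unname(s10),
    chr7_gain = unname(s7 > gain_thresh),
    chr10_loss = unname(s10 < loss_thresh),
    cluster = unname(cluster))
  attr(calls, "chrom_scores") <- tibble::as_tibble(score_mat, rownames = "aoi_id") |>
    tidyr::pivot_longer(-"aoi_id", names_to = "chrom", values_to = "score")
  calls
}
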