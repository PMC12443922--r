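#' Select genes detected above negative-probe background
#'
#' A gene is retained when its expression exceeds the negative-probe
#' background by more than `k` standard deviations, on the mean or on the
#' variance scale: `mean(gene) > m + k * s` or `var(gene) > (m + k * s)^2`,
#' where `m` and `s` are the mean and SD of all negative-probe counts
#' pooled over probes and AOIs (a single global limit of detection). The
#' variance rule is compared against the squared threshold so both arms are
#' in consistent units.
#'
#' @param dataset An [aoi_dataset()].
#' @param k Number of background SDs; default 2.
#' @return Tibble with one row per gene: `gene_id`, `mean`, `var`,
#'   `threshold`, `pass_mean`, `pass_var`, `retained`. The threshold is
#'   attached as attribute `threshold`.
#' @export
filter_genes_by_negative_probes <- function(dataset, k = 2) {
  stopifnot(inherits(dataset, "aoi_dataset"))
  np <- as.numeric(dataset$negprobe_counts)
  if (length(np) < 2) stop("need at least two pooled negative-probe values")
  m_neg <- mean(np)
  s_neg <- stats::sd(np)
  thr <- m_neg + k * s_neg
  mu <- rowMeans(dataset$counts)
  v <- apply(dataset$counts, 1, stats::var)
  out <- tibble::tibble(
    gene_id = dataset$gene_ids,
    mean = mu,
    var = v,
    threshold = thr,
    pass_mean = mu > thr,
    pass_var = v > thr^2,
    retained = mu > thr | v > thr^2)
  attr(out, "threshold") <- thr
  out
}

#' Quantile-normalize counts and move to log2 scale
#'
#' Classic quantile normalization: every AOI's counts are replaced by the
#' across-AOI means of the order statistics, so all columns share one
#' distribution; ties receive the mean of their tied reference quantiles.
#' The normalized values are then transformed to `log2(x + 1)`.
#'
#' @param dataset An [aoi_dataset()] or a numeric genes x AOIs matrix.
#' @param genes Optional character vector of retained gene ids (typically
#'   from [filter_genes_by_negative_probes()]); default all genes.
#' @return A `normalized_matrix`: the log2 matrix with attributes
#'   `normalized`, `batch_corrected` and `retained_genes`.
#' @export
quantile_normalize <- function(dataset, genes = NULL) {
  m <- if (inherits(dataset, "aoi_dataset")) dataset$counts else as.matrix(dataset)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) stop("retained genes absent from counts: ",
                                  paste(utils::head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  qn <- quantile_normalize_core(m)
  out <- log2(qn + 1)
  dimnames(out) <- dimnames(m)
  normalized_matrix(out, normalized = TRUE, batch_corrected = FALSE)
}

## classic quantile normalization with exact tie averaging: every value is
## replaced by the mean of the reference order statistics its tie group
## spans, so all columns share one distribution and the map is idempotent
quantile_normalize_core <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  cum <- cumsum(ref)
  apply(m, 2, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (cum[hi] - c(0, cum)[lo]) / (hi - lo + 1)
  })
}

normalized_matrix <- function(m, normalized, batch_corrected) {
  structure(m,
            normalized = normalized,
            batch_corrected = batch_corrected,
            retained_genes = rownames(m),
            class = c("normalized_matrix", "matrix", "array"))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", nrow(x), " genes x ", ncol(x), " AOIs",
      " (log2 scale; normalized = ", attr(x, "normalized"),
      ", batch_corrected = ", attr(x, "batch_corrected"), ")\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes batch correction of a normalized matrix
#'
#' Removes batch-specific location/scale effects per gene with the
#' parametric empirical-Bayes ComBat model, keeping biological covariates
#' (treatment arm, tumor setting) as protected design columns. A single
#' batch returns the input unchanged; a covariate confounded with batch
#' (nested entirely within one batch) is dropped with a warning.
#'
#' @param norm A `normalized_matrix` from [quantile_normalize()].
#' @param batch Character/factor of batch labels, one per column of `norm`.
#' @param covariates Optional data frame of biological covariates to
#'   protect (e.g. columns `arm`, `setting` of the AOI metadata).
#' @return A `normalized_matrix` with `batch_corrected = TRUE`.
#' @export
correct_batch <- function(norm, batch, covariates = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!isTRUE(attr(norm, "normalized"))) {
    stop("correct_batch expects a quantile-normalized matrix")
  }
  batch <- as.factor(batch)
  if (length(batch) != ncol(norm)) stop("one batch label per AOI required")
  if (nlevels(batch) < 2) {
    return(normalized_matrix(unclass(norm), normalized = TRUE,
                             batch_corrected = TRUE))
  }
  if (any(table(batch) < 2)) stop("every batch needs at least 2 AOIs")

  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(names(covariates), function(nm) {
      f <- as.factor(covariates[[nm]])
      if (nlevels(f) < 2) return(FALSE)
      # confounded: some level observed in a single batch only
      ok <- all(rowSums(table(f, batch) > 0) >= 2)
      if (!ok) warning("covariate '", nm,
                       "' is confounded with batch and was not protected")
      ok
    }, logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates) > 0) {
      mod <- stats::model.matrix(~ ., data = covariates)
    }
  }
  corrected <- sva::ComBat(dat = unclass(norm), batch = batch, mod = mod,
                           par.prior = TRUE, prior.plots = FALSE)
  normalized_matrix(corrected, normalized = TRUE, batch_corrected = TRUE)
}

#' Run the full preprocessing chain
#'
#' Gene filtering against negative probes, then quantile normalization,
#' then batch correction — in that order, with provenance recorded on the
#' result.
#'
#' @param dataset An [aoi_dataset()].
#' @param k Background SD multiplier for the gene filter.
#' @param protect Covariate columns of the AOI metadata shielded during
#'   batch correction.
#' @return List with `norm` (the corrected `normalized_matrix`) and
#'   `gene_filter` (the per-gene filter table).
#' @export
preprocess_dataset <- function(dataset, k = 2, protect = c("arm", "setting")) {
  gf <- filter_genes_by_negative_probes(dataset, k = k)
  norm <- quantile_normalize(dataset, genes = gf$gene_id[gf$retained])
  covs <- dataset$aoi_meta[, intersect(protect, names(dataset$aoi_meta)),
                           drop = FALSE]
  norm <- correct_batch(norm, dataset$aoi_meta$batch, covariates = covs)
  list(norm = norm, gene_filter = gf)
}
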