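#' Classify cells from IHC feature tables
#'
#' Rule-based DAB positivity: a cell enters the denominator when its area
#' is at least `min_area` (cells strictly smaller are artifacts and
#' removed), and an included cell is positive when its mean DAB optical
#' density strictly exceeds `od_threshold`. A cell at exactly the OD
#' threshold is negative.
#'
#' @param cells Tibble with columns `roi_id`, `tumor_id`, `dab_od_mean`,
#'   `area_um2` (one row per cell).
#' @param od_threshold Mean DAB OD positivity threshold (default 0.3).
#' @param min_area Minimum cell area in um^2 (default 20; boundary kept).
#' @return The input tibble with logical columns `included` and `positive`
#'   appended.
#' @export
classify_cells <- function(cells, od_threshold = 0.3, min_area = 20) {
  cells <- tibble::as_tibble(cells)
  needed <- c("roi_id", "tumor_id", "dab_od_mean", "area_um2")
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) stop("cells is missing column(s): ",
                                paste(missing, collapse = ", "))
  if (any(cells$dab_od_mean < 0)) stop("OD values must be >= 0")
  if (any(cells$area_um2 <= 0)) stop("cell areas must be > 0")
  cells |>
    dplyr::mutate(included = .data$area_um2 >= min_area,
                  positive = .data$included & .data$dab_od_mean > od_threshold)
}

#' Per-ROI and per-tumor percent positivity
#'
#' ROI percentage = 100 * positive / included cells; the tumor value is the
#' unweighted mean over its ROIs (each ROI counts equally regardless of
#' cell number). ROIs with no included cell are dropped with a warning;
#' tumors with no valid ROI are absent from the output.
#'
#' @param cells Flagged cell tibble from [classify_cells()].
#' @return List of class `positivity_result`: `roi` (tibble: roi_id,
#'   tumor_id, n_included, n_positive, pct_positive) and `tumor` (tibble:
#'   tumor_id, n_rois, pct_positive).
#' @export
percent_positive <- function(cells) {
  if (!all(c("included", "positive") %in% names(cells))) {
    stop("run classify_cells() first")
  }
  roi <- cells |>
    dplyr::group_by(.data$roi_id, .data$tumor_id) |>
    dplyr::summarise(n_included = sum(.data$included),
                     n_positive = sum(.data$positive), .groups = "drop")
  empty <- roi$n_included == 0
  if (any(empty)) {
    warning(sum(empty), " ROI(s) with no included cells dropped: ",
            paste(utils::head(roi$roi_id[empty], 5), collapse = ", "))
    roi <- roi[!empty, , drop = FALSE]
  }
  roi$pct_positive <- 100 * roi$n_positive / roi$n_included
  tumor <- roi |>
    dplyr::group_by(.data$tumor_id) |>
    dplyr::summarise(n_rois = dplyr::n(),
                     pct_positive = mean(.data$pct_positive), .groups = "drop")
  structure(list(roi = roi, tumor = tumor), class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat("<positivity_result> ", nrow(x$roi), " ROIs, ", nrow(x$tumor),
      " tumors\n", sep = "")
  print(x$tumor)
  invisible(x)
}

#' Group comparisons of tumor-level positivity
#'
#' Paired exact Wilcoxon signed-rank tests of primary vs recurrent tumors
#' within each arm (patients with both settings), and an unpaired Wilcoxon
#' rank-sum test of treated vs control recurrences. Medians and
#' interquartile ranges accompany every p-value.
#'
#' @param result A `positivity_result` from [percent_positive()].
#' @param design Tibble mapping tumors to the trial design: columns
#'   `tumor_id`, `patient_id`, `setting`, `arm`.
#' @param min_pairs Minimum number of complete pairs per paired test.
#' @return Tibble with one row per comparison: `comparison`, `arm`, `test`,
#'   `n`, `median_a`, `iqr_a`, `median_b`, `iqr_b`, `p_value`.
#' @export
compare_groups <- function(result, design, min_pairs = 2) {
  stopifnot(inherits(result, "positivity_result"))
  tab <- dplyr::inner_join(result$tumor, tibble::as_tibble(design),
                           by = "tumor_id")
  rows <- list()
  for (arm in unique(tab$arm)) {
    sub <- tab[tab$arm == arm, ]
    wide <- sub |>
      dplyr::select("patient_id", "setting", "pct_positive") |>
      tidyr::pivot_wider(names_from = "setting", values_from = "pct_positive")
    if (!all(c("primary", "recurrent") %in% names(wide))) next
    wide <- wide[stats::complete.cases(wide[, c("primary", "recurrent")]), ]
    if (nrow(wide) < min_pairs) {
      stop("fewer than ", min_pairs, " complete primary/recurrent pairs in arm '",
           arm, "'")
    }
    wt <- wilcoxon_signed_rank_exact(wide$recurrent, wide$primary)
    rows[[paste0("paired_", arm)]] <- tibble::tibble(
      comparison = "primary_vs_recurrent", arm = arm, test = "signed_rank",
      n = nrow(wide),
      median_a = stats::median(wide$primary),
      iqr_a = stats::IQR(wide$primary),
      median_b = stats::median(wide$recurrent),
      iqr_b = stats::IQR(wide$recurrent),
      p_value = wt$p_value)
  }
  rec <- tab[tab$setting == "recurrent", ]
  if (all(c("treated", "control") %in% rec$arm)) {
    xt <- rec$pct_positive[rec$arm == "treated"]
    xc <- rec$pct_positive[rec$arm == "control"]
    rt <- wilcoxon_rank_sum(xt, xc)
    rows[["recurrent_arms"]] <- tibble::tibble(
      comparison = "treated_vs_control_recurrent", arm = "both",
      test = "rank_sum", n = length(xt) + length(xc),
      median_a = stats::median(xt), iqr_a = stats::IQR(xt),
      median_b = stats::median(xc), iqr_b = stats::IQR(xc),
      p_value = rt$p_value)
  }
  dplyr::bind_rows(rows)
}
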