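#' Two-step purity classification of SOX2+ AOIs
#'
#' Implements the tumor-purity filter for tumor-cell segments: an AOI is
#' excluded only when all three hold — (1) it carries neither hallmark
#' alteration (no chr7 gain, no chr10 loss), (2) a non-malignant signature
#' dominates (oligodendrocyte or TAM Z above `z_nonmalig_thresh`), and
#' (3) no malignant cell state is expressed (max malignant-state Z below
#' `z_malig_thresh`). Copy-number evidence always dominates: an AOI with a
#' hallmark call is never excluded. The max over malignant states is used
#' because a tumor cell need only express one state.
#'
#' @param cnv_calls Hallmark call tibble from [score_and_call()].
#' @param scores Long score tibble from [aggregate_zscore()], covering the
#'   same AOIs; must contain at least one `malignant_state` signature and
#'   the two non-malignant panels named by `oligo_signature` /
#'   `tam_signature`.
#' @param z_nonmalig_thresh Z above which a non-malignant signature counts
#'   as dominant (default 1).
#' @param z_malig_thresh Z below which malignant states count as absent
#'   (default 0).
#' @param oligo_signature,tam_signature Names of the non-malignant panels.
#' @return Tibble of purity calls: `aoi_id`, `decision` ("keep"/"exclude"),
#'   `has_hallmark_cnv`, `max_malignant_z`, `oligo_z`, `tam_z`, `rule`.
#' @export
classify_sox2_aois <- function(cnv_calls, scores,
                               z_nonmalig_thresh = 1.0,
                               z_malig_thresh = 0.0,
                               oligo_signature = "oligodendrocyte",
                               tam_signature = "tam") {
  aois <- unique(scores$aoi_id)
  missing <- setdiff(aois, cnv_calls$aoi_id)
  if (length(missing) > 0) stop("AOIs scored but absent from CNV calls: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  mal <- scores[scores$role == "malignant_state", ]
  if (nrow(mal) == 0) stop("no malignant_state signatures in scores")
  for (sig in c(oligo_signature, tam_signature)) {
    if (!sig %in% scores$signature) stop("signature missing from scores: ", sig)
  }

  wide <- tibble::tibble(aoi_id = aois) |>
    dplyr::left_join(
      mal |> dplyr::group_by(.data$aoi_id) |>
        dplyr::summarise(max_malignant_z = max(.data$score), .groups = "drop"),
      by = "aoi_id") |>
    dplyr::left_join(
      scores |> dplyr::filter(.data$signature == oligo_signature) |>
        dplyr::select("aoi_id", oligo_z = "score"), by = "aoi_id") |>
    dplyr::left_join(
      scores |> dplyr::filter(.data$signature == tam_signature) |>
        dplyr::select("aoi_id", tam_z = "score"), by = "aoi_id") |>
    dplyr::left_join(cnv_calls[, c("aoi_id", "chr7_gain", "chr10_loss")],
                     by = "aoi_id")

  wide |>
    dplyr::mutate(
      has_hallmark_cnv = .data$chr7_gain | .data$chr10_loss,
      nonmalig_dominant = .data$oligo_z > z_nonmalig_thresh |
        .data$tam_z > z_nonmalig_thresh,
      malig_absent = .data$max_malignant_z < z_malig_thresh,
      decision = ifelse(!.data$has_hallmark_cnv & .data$nonmalig_dominant &
                          .data$malig_absent, "exclude", "keep"),
      rule = dplyr::case_when(
        has_hallmark_cnv ~ "hallmark_cnv_present",
        decision == "exclude" ~ "non_malignant_dominant",
        nonmalig_dominant & !malig_absent ~ "malignant_state_expressed",
        TRUE ~ "no_exclusion_evidence")) |>
    dplyr::select("aoi_id", "decision", "has_hallmark_cnv",
                  "max_malignant_z", "oligo_z", "tam_z", "rule")
}

#' Filter IBA1+ AOIs by TAM signature Z-score
#'
#' Macrophage/microglia segments are kept when their TAM signature Z-score
#' is at or above `tam_z_thresh` within the IBA1+ population.
#'
#' @param scores Long score tibble from [aggregate_zscore()] computed on
#'   the IBA1+ population.
#' @param tam_z_thresh Keep threshold (default 0; `>=` convention).
#' @param tam_signature Name of the TAM signature.
#' @return Tibble: `aoi_id`, `decision`, `tam_z`, `rule`.
#' @export
filter_iba1_aois <- function(scores, tam_z_thresh = 0.0,
                             tam_signature = "tam") {
  tam <- scores[scores$signature == tam_signature, ]
  if (nrow(tam) == 0) stop("signature missing from scores: ", tam_signature)
  tibble::tibble(
    aoi_id = tam$aoi_id,
    decision = ifelse(tam$score >= tam_z_thresh, "keep", "exclude"),
    tam_z = tam$score,
    rule = ifelse(tam$score >= tam_z_thresh, "tam_signature_present",
                  "tam_signature_low"))
}

#' Per-tumor exclusion report
#'
#' A tumor is flagged excluded when none of its SOX2+ AOIs survives the
#' purity filter; exclusion counts are summarized per arm and setting.
#'
#' @param calls Purity-call tibble from [classify_sox2_aois()] (SOX2+
#'   AOIs).
#' @param aoi_meta AOI metadata.
#' @return List of class `exclusion_report` with `tumors` (one row per
#'   tumor: kept/total AOI counts, `excluded` flag) and `by_group`
#'   (counts per arm x setting).
#' @export
exclusion_report <- function(calls, aoi_meta) {
  tab <- calls |>
    dplyr::left_join(aoi_meta[, c("aoi_id", "tumor_id", "patient_id",
                                  "setting", "arm")], by = "aoi_id")
  tumors <- tab |>
    dplyr::group_by(.data$tumor_id, .data$patient_id, .data$setting, .data$arm) |>
    dplyr::summarise(n_aois = dplyr::n(),
                     n_kept = sum(.data$decision == "keep"),
                     .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_kept == 0)
  by_group <- tumors |>
    dplyr::group_by(.data$arm, .data$setting) |>
    dplyr::summarise(n_tumors = dplyr::n(),
                     n_excluded = sum(.data$excluded), .groups = "drop")
  structure(list(tumors = tumors, by_group = by_group),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> ", sum(x$tumors$excluded), " of ",
      nrow(x$tumors), " tumors excluded (no surviving SOX2+ AOIs)\n", sep = "")
  print(x$by_group)
  invisible(x)
}
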