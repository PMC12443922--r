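mock_scores <- function(df) {
  # df: aoi_id, mal (max malignant), oligo, tam
  dplyr::bind_rows(
    tibble::tibble(aoi_id = df$aoi_id, signature = "MES",
                   role = "malignant_state", score = df$mal),
    tibble::tibble(aoi_id = df$aoi_id, signature = "oligodendrocyte",
                   role = "non_malignant", score = df$oligo),
    tibble::tibble(aoi_id = df$aoi_id, signature = "tam",
                   role = "non_malignant", score = df$tam))
}

mock_calls <- function(aoi_id, gain = FALSE, loss = FALSE) {
  tibble::tibble(aoi_id = aoi_id, score_chr7 = 0, score_chr10 = 0,
                 chr7_gain = gain, chr10_loss = loss, cluster = 1L)
}

test_that("the exclusion rule table is applied as specified", {
  df <- tibble::tibble(
    aoi_id = c("cnv_pos", "contam", "malig", "ambig"),
    mal = c(-1, -1, 0.5, 0.5),
    oligo = c(3, 2.5, 2.5, 0.2),
    tam = c(0, 0.3, 0.1, 0.4))
  calls <- mock_calls(df$aoi_id, gain = c(TRUE, FALSE, FALSE, FALSE))
  out <- classify_sox2_aois(calls, mock_scores(df))
  out <- out[match(df$aoi_id, out$aoi_id), ]
  # hallmark CNV evidence dominates any signature configuration
  expect_identical(out$decision, c("keep", "exclude", "keep", "keep"))
  expect_identical(out$rule, c("hallmark_cnv_present", "non_malignant_dominant",
                               "malignant_state_expressed",
                               "no_exclusion_evidence"))
})

test_that("an AOI scored but missing from CNV calls is an error", {
  df <- tibble::tibble(aoi_id = c("a1", "a2"), mal = 0, oligo = 0, tam = 0)
  expect_error(classify_sox2_aois(mock_calls("a1"), mock_scores(df)), "a2")
})

test_that("raising the non-malignant threshold never adds exclusions", {
  set.seed(8)
  df <- tibble::tibble(aoi_id = sprintf("a%02d", 1:40),
                       mal = rnorm(40), oligo = rnorm(40), tam = rnorm(40))
  calls <- mock_calls(df$aoi_id, gain = runif(40) < 0.3)
  n_excl <- vapply(c(0.5, 1, 1.5, 2), function(th) {
    sum(classify_sox2_aois(calls, mock_scores(df),
                           z_nonmalig_thresh = th)$decision == "exclude")
  }, numeric(1))
  expect_true(all(diff(n_excl) <= 0))
})

test_that("purity-0 AOIs are excluded and tumors recovered on planted truth", {
  co <- default_cohort()
  prof <- compute_cnv_profile(co$pre$norm, co$sim$annotation,
                              reference_aois = co$iba1, query_aois = co$sox2)
  calls <- score_and_call(prof)
  scores <- suppressWarnings(
    aggregate_zscore(co$pre$norm, co$sim$signatures, population = co$sox2))
  pc <- classify_sox2_aois(calls, scores)
  truth <- co$sim$truth$aoi[match(pc$aoi_id, co$sim$truth$aoi$aoi_id), ]
  p0 <- truth$malignant_fraction == 0
  expect_gte(mean(pc$decision[p0] == "exclude"), 0.9)     # sensitivity
  expect_gte(mean(pc$decision[!p0] == "keep"), 0.95)      # specificity
  # invariant: no AOI with hallmark evidence is ever excluded
  expect_false(any(pc$decision == "exclude" & pc$has_hallmark_cnv))
})

test_that("IBA1 filtering keeps AOIs at or above the TAM Z threshold", {
  sc <- tibble::tibble(aoi_id = c("i1", "i2", "i3"), signature = "tam",
                       role = "non_malignant", score = c(0, 0, 0))
  out <- filter_iba1_aois(sc, tam_z_thresh = 0)
  expect_true(all(out$decision == "keep"))   # >= convention at the boundary

  # an oligodendrocyte-dominated AOI scores below the IBA1 population mean
  co <- default_cohort()
  norm <- co$pre$norm
  oligo_genes <- intersect(co$sim$signatures$sets$oligodendrocyte,
                           rownames(norm))
  tam_genes <- intersect(co$sim$signatures$sets$tam, rownames(norm))
  fake <- unclass(norm)[, co$iba1]
  fake[, 1] <- rowMeans(unclass(norm)[, co$iba1])
  fake[oligo_genes, 1] <- fake[oligo_genes, 1] + 3
  fake[tam_genes, 1] <- fake[tam_genes, 1] - 3
  sc2 <- suppressWarnings(
    aggregate_zscore(as_norm(fake), co$sim$signatures))
  out2 <- filter_iba1_aois(sc2)
  expect_identical(out2$decision[1], "exclude")

  out3 <- filter_iba1_aois(sc2, tam_z_thresh = -Inf)
  expect_true(all(out3$decision == "keep"))
})

test_that("tumors lose their excluded status only with surviving AOIs", {
  meta <- tibble::tibble(
    aoi_id = c("a1", "a2", "b1", "b2", "b3"),
    tumor_id = c("tA", "tA", "tB", "tB", "tB"),
    patient_id = c("p1", "p1", "p2", "p2", "p2"),
    setting = "recurrent",
    arm = c("control", "control", "treated", "treated", "treated"))
  calls <- tibble::tibble(
    aoi_id = meta$aoi_id,
    decision = c("keep", "exclude", "exclude", "exclude", "exclude"),
    has_hallmark_cnv = FALSE, max_malignant_z = 0, oligo_z = 0, tam_z = 0,
    rule = "non_malignant_dominant")
  rep <- exclusion_report(calls, meta)
  expect_identical(rep$tumors$excluded[rep$tumors$tumor_id == "tA"], FALSE)
  expect_identical(rep$tumors$excluded[rep$tumors$tumor_id == "tB"], TRUE)
  bg <- rep$by_group
  expect_equal(bg$n_excluded[bg$arm == "treated"], 1)
  expect_equal(bg$n_excluded[bg$arm == "control"], 0)
})

test_that("a deliberately zero-purity tumor is the one flagged", {
  co <- default_cohort()
  prof <- compute_cnv_profile(co$pre$norm, co$sim$annotation,
                              reference_aois = co$iba1, query_aois = co$sox2)
  calls <- score_and_call(prof)
  scores <- suppressWarnings(
    aggregate_zscore(co$pre$norm, co$sim$signatures, population = co$sox2))
  pc <- classify_sox2_aois(calls, scores)
  truth <- co$sim$truth$aoi
  zero_tumors <- truth |>
    dplyr::filter(.data$segment == "SOX2") |>
    dplyr::group_by(.data$tumor_id) |>
    dplyr::summarise(all_zero = all(.data$malignant_fraction == 0))
  rep <- exclusion_report(pc, co$sim$dataset$aoi_meta)
  joined <- dplyr::left_join(rep$tumors, zero_tumors, by = "tumor_id")
  # every all-zero-purity tumor is flagged; others are not
  expect_true(all(joined$excluded[joined$all_zero]))
  expect_false(any(joined$excluded[!joined$all_zero]))
})
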