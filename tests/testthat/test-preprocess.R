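make_ds <- function(counts, negprobes) {
  n <- ncol(counts)
  meta <- tibble::tibble(aoi_id = colnames(counts),
                         roi_id = paste0("r", seq_len(n)),
                         core_id = "c1", tumor_id = "t1", patient_id = "p1",
                         setting = "primary", arm = "control",
                         segment = "SOX2", batch = "batch1")
  aoi_dataset(counts, negprobes, meta)
}

test_that("negative-probe gene filter follows the two-SD rule", {
  aois <- paste0("a", 1:3)
  # pooled negprobes {8, 10, 12}: m = 10, s = 2, threshold = 14
  np <- matrix(c(8, 10, 12), 1, 3, dimnames = list("np1", aois))
  cnt <- rbind(g13 = c(13, 13, 13), g15 = c(15, 15, 15))
  colnames(cnt) <- aois
  res <- filter_genes_by_negative_probes(make_ds(cnt, np), k = 2)
  expect_equal(attr(res, "threshold"), 14)
  expect_false(res$retained[res$gene_id == "g13"])  # 13 < 14, var 0
  expect_true(res$retained[res$gene_id == "g15"])

  # zero-SD background: threshold equals the background mean
  np0 <- matrix(10, 2, 3, dimnames = list(c("np1", "np2"), aois))
  cnt0 <- rbind(g11 = c(11, 11, 11), g0 = c(0, 0, 0))
  colnames(cnt0) <- aois
  res0 <- filter_genes_by_negative_probes(make_ds(cnt0, np0), k = 2)
  expect_true(res0$retained[res0$gene_id == "g11"])
  expect_false(res0$retained[res0$gene_id == "g0"])

  # the variance arm alone can retain a gene: mean 10 < 14, var 300 > 196
  cntv <- rbind(gvar = c(0, 0, 30), gflat = c(1, 1, 1))
  colnames(cntv) <- aois
  resv <- filter_genes_by_negative_probes(make_ds(cntv, np), k = 2)
  expect_true(resv$retained[resv$gene_id == "gvar"])
  expect_true(resv$pass_var[resv$gene_id == "gvar"])
  expect_false(resv$pass_mean[resv$gene_id == "gvar"])
  expect_false(resv$retained[resv$gene_id == "gflat"])

  # a single pooled background value is not enough for an SD
  np1 <- matrix(10, 1, 1, dimnames = list("np1", "a1"))
  cnt1 <- matrix(5, 2, 1, dimnames = list(c("g1", "g2"), "a1"))
  expect_error(filter_genes_by_negative_probes(make_ds(cnt1, np1)),
               "at least two")
})

test_that("quantile normalization matches the hand-computed example", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  qn <- quantile_normalize(m)
  pre_log <- 2^unclass(qn) - 1
  expect_equal(unname(pre_log), matrix(c(2.5, 3.5, 4.5), 3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("quantile normalization yields one shared column distribution", {
  set.seed(42)
  m <- matrix(exp(rnorm(300 * 8, 3, 1)), 300, 8,    # tie-free values
              dimnames = list(paste0("g", 1:300), paste0("a", 1:8)))
  m[, 3] <- m[, 3] * 4                      # strong library-size bias
  qn <- 2^unclass(quantile_normalize(m)) - 1
  ref <- unname(sort(qn[, 1]))
  for (j in 2:ncol(qn)) {
    expect_equal(unname(sort(qn[, j])), ref, tolerance = 1e-12)
  }

  # idempotence on the pre-log scale
  qn2 <- 2^unclass(quantile_normalize(qn)) - 1
  expect_equal(unname(qn2), unname(qn), tolerance = 1e-9)

  # ties receive the mean of their tied reference quantiles:
  # ref = (sort(c1) + sort(c2)) / 2 = (2.5, 3, 4); the tied 1s share
  # mean(2.5, 3) = 2.75
  mt <- cbind(c1 = c(1, 1, 2), c2 = c(4, 5, 6))
  rownames(mt) <- paste0("g", 1:3)
  qt <- 2^unclass(quantile_normalize(mt)) - 1
  expect_equal(unname(qt[, "c1"]), c(2.75, 2.75, 4), tolerance = 1e-12)
  expect_equal(unname(qt[, "c2"]), c(2.5, 3, 4), tolerance = 1e-12)

  # identical columns stay identical; an all-zero column is allowed and,
  # being one big tie, maps to the mean of the reference quantiles
  m2 <- cbind(a = c(5, 1, 9), b = c(5, 1, 9), z = c(0, 0, 0))
  rownames(m2) <- paste0("g", 1:3)
  qn3 <- 2^unclass(quantile_normalize(m2)) - 1
  expect_equal(qn3[, "a"], qn3[, "b"])
  ref3 <- c(2 / 3, 10 / 3, 6)   # rowMeans of the sorted columns
  expect_equal(unname(sort(qn3[, "a"])), ref3, tolerance = 1e-12)
  expect_equal(unname(qn3[, "z"]), rep(mean(ref3), 3), tolerance = 1e-12)
})

test_that("batch correction removes a planted constant shift", {
  ng <- 200; n_per <- 8
  mu_g <- seq(4, 12, length.out = ng)
  s <- seq(-1, 1, length.out = n_per)       # same within-batch pattern per gene
  base <- outer(mu_g, rep(1, 2 * n_per)) +
    cbind(matrix(rep(s, each = ng), ng), matrix(rep(s, each = ng), ng))
  base[, (n_per + 1):(2 * n_per)] <- base[, (n_per + 1):(2 * n_per)] + 0.7
  dimnames(base) <- list(paste0("g", 1:ng), paste0("a", 1:(2 * n_per)))
  batch <- rep(c("b1", "b2"), each = n_per)
  cb <- unclass(correct_batch(as_norm(base), batch))
  bm_diff <- rowMeans(cb[, batch == "b1"]) - rowMeans(cb[, batch == "b2"])
  expect_lt(max(abs(bm_diff)), 1e-6)
  # per-gene grand means are preserved in this construction
  expect_lt(max(abs(rowMeans(cb) - rowMeans(base))), 1e-6)
})

test_that("single batch and confounded covariates are handled", {
  m <- matrix(rnorm(50 * 6, 8), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("a", 1:6)))
  nm <- as_norm(m)
  expect_equal(unclass(correct_batch(nm, rep("b1", 6))), m,
               ignore_attr = TRUE)
  expect_true(attr(correct_batch(nm, rep("b1", 6)), "batch_corrected"))

  # covariate nested within batch cannot be protected
  covs <- data.frame(arm = c("t", "t", "t", "c", "c", "c"))
  expect_warning(correct_batch(nm, c("b1", "b1", "b1", "b2", "b2", "b2"),
                               covariates = covs), "confounded")
})

test_that("preprocessing runs filter, normalization, correction in order", {
  sim <- small_cohort()
  pre <- suppressWarnings(preprocess_dataset(sim$dataset))
  expect_true(attr(pre$norm, "normalized"))
  expect_true(attr(pre$norm, "batch_corrected"))
  retained <- pre$gene_filter$gene_id[pre$gene_filter$retained]
  expect_identical(rownames(pre$norm), retained)
  expect_lt(length(retained), nrow(sim$dataset$counts))
  # unexpressed genes are the ones the background filter removes
  gf <- dplyr::left_join(pre$gene_filter, sim$truth$gene, by = "gene_id")
  expect_gt(mean(gf$retained[gf$expressed]), 0.95)
  expect_lt(mean(gf$retained[!gf$expressed]), 0.05)
})
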