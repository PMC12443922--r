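test_that("pseudobulk sums counts per tumor and matches a brute-force oracle", {
  sim <- small_cohort()
  pb <- pseudobulk(sim$dataset, segment = "SOX2")
  meta <- sim$dataset$aoi_meta
  for (tm in colnames(pb$counts)[1:5]) {
    aois <- meta$aoi_id[meta$tumor_id == tm & meta$segment == "SOX2"]
    expect_equal(pb$counts[, tm],
                 rowSums(sim$dataset$counts[, aois, drop = FALSE]))
  }
  # a single surviving AOI is the identity
  one <- meta$aoi_id[meta$segment == "SOX2"][1]
  pb1 <- pseudobulk(sim$dataset, keep_aois = one, segment = "SOX2")
  expect_equal(unname(pb1$counts[, 1]), unname(sim$dataset$counts[, one]))
})

test_that("BH adjustment matches hand arithmetic and dominates raw p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(1)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("NB Wald DE recovers a planted fold change and stays label-free", {
  set.seed(2100)
  mu <- exp(rnorm(1500, 5, 1.5))
  cnt <- matrix(rnbinom(1500 * 12, mu = rep(mu, 12), size = 10), 1500,
                dimnames = list(sprintf("G%04d", 1:1500), paste0("T", 1:12)))
  cnt[1:100, 7:12] <- matrix(
    rnbinom(100 * 6, mu = rep(2 * mu[1:100], 6), size = 10), 100)
  cond <- rep(c("control", "treated"), each = 6)
  de <- nb_wald_de(cnt, cond)
  expect_lt(abs(stats::median(de$table$log2fc[1:100]) - 1), 0.2)
  # q-values are a monotone transform of p-values
  ord <- order(de$table$pvalue)
  expect_true(all(diff(de$table$qvalue[ord]) >= -1e-12))
  # size factors ignore the condition labels
  de_perm <- nb_wald_de(cnt, rep(c("control", "treated"), 6))
  expect_equal(de_perm$size_factors, de$size_factors)
  # size factors: positive, geometric mean 1
  expect_true(all(de$size_factors > 0))
  expect_equal(exp(mean(log(de$size_factors))), 1, tolerance = 1e-12)
  # doubling all counts doubles nothing that matters
  de2 <- nb_wald_de(cnt * 2, cond)
  expect_lt(max(abs(de2$table$log2fc - de$table$log2fc)), 0.02)
  # all-zero genes are excluded and counted
  cnt0 <- rbind(cnt, Gzero = 0L)
  de0 <- nb_wald_de(cnt0, cond)
  expect_false("Gzero" %in% de0$table$gene_id)
  expect_equal(attr(de0, "n_zero_genes"), 1L)
})

test_that("NB Wald DE agrees with an independent NB GLM implementation", {
  set.seed(33)
  mu <- exp(rnorm(400, 5, 1))
  cnt <- matrix(rnbinom(400 * 10, mu = rep(mu, 10), size = 10), 400,
                dimnames = list(sprintf("G%03d", 1:400), paste0("T", 1:10)))
  cnt[1:50, 6:10] <- matrix(
    rnbinom(50 * 5, mu = rep(3 * mu[1:50], 5), size = 10), 50)
  cond <- rep(c("a", "b"), each = 5)
  de <- nb_wald_de(cnt, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = cnt, colData = S4Vectors::DataFrame(condition = factor(cond)),
    design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, minReplicatesForReplace = Inf)
  res <- DESeq2::results(dds, contrast = c("condition", "b", "a"),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  expect_gt(stats::cor(de$table$log2fc, res$log2FoldChange), 0.98)
  expect_lt(stats::median(abs(de$table$log2fc - res$log2FoldChange)), 0.05)
  # both see the planted 3x genes
  expect_lt(abs(stats::median(de$table$log2fc[1:50]) - log2(3)), 0.25)
})

test_that("the mixed model reproduces the paired t test on balanced pairs", {
  set.seed(11)
  n <- 12
  pat <- factor(rep(1:n, each = 2))
  grp <- factor(rep(c("A", "B"), n))
  y <- rnorm(n, sd = 1.5)[pat] + (grp == "B") * 0.5 + rnorm(2 * n, 0, 0.3)
  fit <- fit_random_intercept(data.frame(y = y, group = grp, patient = pat))
  td <- tidy(fit)
  tt <- stats::t.test(y[grp == "B"], y[grp == "A"], paired = TRUE)
  expect_lt(abs(td$statistic[2] - unname(tt$statistic)), 1e-8)
  expect_equal(td$df[2], n - 1, tolerance = 1e-6)
  # with two groups Tukey reduces to the unadjusted comparison
  emm <- emmeans_tukey(fit)
  expect_equal(emm$contrasts$p_value, td$p_value[2], tolerance = 1e-8)
  expect_equal(abs(emm$contrasts$estimate),
               abs(unname(tt$estimate)), tolerance = 1e-8)
})

test_that("zero between-patient variance collapses to OLS", {
  # patient sums are constant, so the between-patient variance component
  # sits exactly at its zero boundary
  set.seed(12)
  n <- 20
  d <- rnorm(n)
  grp <- factor(rep(c("A", "B"), n))
  pat <- factor(rep(1:n, each = 2))
  y <- as.vector(rbind(5 - d / 2, 5 + d / 2)) + (grp == "B") * 1
  fit <- fit_random_intercept(data.frame(y = y, group = grp, patient = pat))
  gl <- glance(fit)
  ols <- stats::lm(y ~ grp)
  expect_lt(gl$var_patient, 1e-6)
  expect_equal(unname(tidy(fit)$estimate),
               unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("a constant response yields zero contrasts", {
  d <- data.frame(y = 1, group = rep(c("A", "B"), 6),
                  patient = rep(1:6, each = 2))
  fit <- suppressWarnings(
    suppressMessages(fit_random_intercept(d)))
  emm <- suppressWarnings(emmeans_tukey(fit))
  expect_equal(emm$contrasts$estimate, 0, tolerance = 1e-12)
})

test_that("four-group marginal means honour the design and Tukey dominates", {
  set.seed(13)
  n_pat <- 16
  pat <- factor(rep(1:n_pat, each = 2))
  grp <- factor(rep(c("t_pri", "t_rec", "c_pri", "c_rec"), n_pat / 2))
  y <- rnorm(n_pat, sd = 1)[pat] + rnorm(2 * n_pat, 0, 0.5)
  fit <- fit_random_intercept(data.frame(y = y, group = grp, patient = pat))
  emm <- emmeans_tukey(fit)
  expect_equal(nrow(emm$contrasts), 6)
  raw_p <- 2 * stats::pt(-abs(emm$contrasts$t_ratio), emm$contrasts$df)
  expect_true(all(emm$contrasts$p_value >= raw_p - 1e-12))
})

test_that("exact signed-rank reproduces the small-sample extremes", {
  out <- wilcoxon_signed_rank_exact(rep(1, 7))
  expect_equal(out$p_value, 0.015625)
  expect_equal(round(out$p_value, 4), 0.0156)
  expect_equal(wilcoxon_signed_rank_exact(5)$p_value, 1)       # n = 1
  expect_warning(out0 <- wilcoxon_signed_rank_exact(c(0, 0)), "zero")
  expect_equal(out0$p_value, 1)
  # agrees with the classical exact distribution when ties are absent
  set.seed(14)
  d <- rnorm(10)
  expect_equal(wilcoxon_signed_rank_exact(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("exact tests match brute-force enumeration, ties included", {
  set.seed(15)
  for (i in 1:6) {
    d <- sample(c(-4:-1, 1:4), 8, replace = TRUE)   # midrank ties likely
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  for (i in 1:4) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  x <- rnorm(5)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})
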