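#' Aggregate AOI counts into tumor-level pseudobulk
#'
#' Sums raw (pre-normalization) counts over each tumor's surviving AOIs of
#' one segment type, yielding one column per tumor.
#'
#' @param dataset An [aoi_dataset()] (raw counts).
#' @param keep_aois Optional character vector of surviving AOI ids.
#' @param segment Segment type to aggregate ("SOX2" or "IBA1").
#' @return List of class `pseudobulk`: `counts` (genes x tumors integer
#'   matrix) and `tumors` (tibble: tumor_id, patient_id, setting, arm,
#'   n_aois).
#' @export
pseudobulk <- function(dataset, keep_aois = NULL, segment = "SOX2") {
  stopifnot(inherits(dataset, "aoi_dataset"))
  meta <- dataset$aoi_meta
  sel <- meta$segment == segment
  if (!is.null(keep_aois)) sel <- sel & meta$aoi_id %in% keep_aois
  meta <- meta[sel, , drop = FALSE]
  if (nrow(meta) == 0) stop("no AOIs selected for pseudobulk aggregation")
  tum_ids <- unique(meta$tumor_id)
  counts <- vapply(tum_ids, function(tm) {
    rowSums(dataset$counts[, meta$aoi_id[meta$tumor_id == tm], drop = FALSE])
  }, numeric(nrow(dataset$counts)))
  tumors <- meta |>
    dplyr::group_by(.data$tumor_id, .data$patient_id, .data$setting, .data$arm) |>
    dplyr::summarise(n_aois = dplyr::n(), .groups = "drop")
  tumors <- tumors[match(tum_ids, tumors$tumor_id), ]
  structure(list(counts = counts, tumors = tumors), class = "pseudobulk")
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor = median over genes of the ratio of the sample's
#' count to the gene's geometric mean across samples, computed on genes
#' with all-positive counts; size factors are rescaled to geometric mean 1.
#' When fewer than 10 genes have all-positive counts, gene geometric means
#' are taken over positive counts only, with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @return Positive numeric vector, one size factor per sample.
#' @export
size_factors_mor <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(all_pos) >= 10) {
    logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2, function(y) {
      exp(stats::median(log(y) - logref))
    })
  } else {
    warning("fewer than 10 all-positive genes; ",
            "using positive-count-only geometric means")
    pos <- counts > 0
    logref <- rowSums(log(pmax(counts, 1)) * pos) / pmax(rowSums(pos), 1)
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      keep <- pos[, j]
      exp(stats::median(log(counts[keep, j]) - logref[keep]))
    }, numeric(1))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

## Fisher-scoring fit of per-gene NB GLM log(mu) = log(sf) + b0 + b1*x for
## a binary design, vectorized over genes. Returns b0, b1 and the Wald SE
## of b1 (natural-log scale).
nb_glm_two_group <- function(counts, sf, x, phi, n_iter = 30) {
  n_g <- nrow(counts)
  sf_mat <- matrix(sf, n_g, length(sf), byrow = TRUE)
  x_mat <- matrix(x, n_g, length(x), byrow = TRUE)
  m0 <- rowSums(counts[, x == 0, drop = FALSE]) / sum(sf[x == 0])
  m1 <- rowSums(counts[, x == 1, drop = FALSE]) / sum(sf[x == 1])
  eps0 <- 0.5 / sum(sf[x == 0]); eps1 <- 0.5 / sum(sf[x == 1])
  b0 <- log(pmax(m0, eps0))
  b1 <- log(pmax(m1, eps1)) - b0
  for (it in seq_len(n_iter)) {
    mu <- sf_mat * exp(b0 + b1 * x_mat)
    w <- mu / (1 + phi * mu)
    r <- (counts - mu) / (1 + phi * mu)
    u0 <- rowSums(r); u1 <- rowSums(r * x_mat)
    i00 <- rowSums(w); i01 <- rowSums(w * x_mat); i11 <- i01
    det <- pmax(i00 * i11 - i01^2, 1e-300)
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    d0 <- pmin(pmax(d0, -5), 5); d1 <- pmin(pmax(d1, -5), 5)
    b0 <- b0 + d0; b1 <- b1 + d1
  }
  mu <- sf_mat * exp(b0 + b1 * x_mat)
  w <- mu / (1 + phi * mu)
  i00 <- rowSums(w); i01 <- rowSums(w * x_mat); i11 <- i01
  det <- pmax(i00 * i11 - i01^2, 1e-300)
  list(b0 = b0, b1 = b1, se_b1 = sqrt(i00 / det), mu = mu)
}

## Cox-Reid adjusted profile log-likelihood of the NB dispersion for one
## gene, means held fixed.
nb_apl <- function(phi, y, mu, x) {
  a <- 1 / phi
  ll <- sum(lgamma(y + a) - lgamma(a) - lgamma(y + 1) +
              a * log(a / (a + mu)) + y * log(mu / (a + mu)))
  w <- mu / (1 + phi * mu)
  i00 <- sum(w); i01 <- sum(w * x); i11 <- i01
  ll - 0.5 * log(max(i00 * i11 - i01^2, 1e-300))
}

#' Negative-binomial Wald differential expression on pseudobulk counts
#'
#' Tumor-level two-group DE with the standard NB GLM workflow:
#' median-of-ratios size factors ([size_factors_mor()]); per-gene NB GLM
#' with log link (intercept + condition) fitted by Fisher scoring;
#' gene-wise dispersions by Cox-Reid-adjusted profile likelihood, shrunk
#' toward a fitted parametric mean-dispersion trend
#' (`a0 + a1 / mean`) as a weighted average in log-dispersion space; Wald
#' test on the condition coefficient; Benjamini-Hochberg adjustment. No
#' independent filtering or outlier replacement, so results are a
#' deterministic function of the counts. Genes with all-zero counts are
#' excluded and reported via the `n_zero_genes` attribute.
#'
#' @param counts Genes x tumors count matrix (or a `pseudobulk` object).
#' @param condition Factor/character of length `ncol(counts)`; the
#'   reported log2 fold change is level 2 vs level 1 of
#'   `factor(condition)`.
#' @param prior_weight Weight of the trend in the log-scale dispersion
#'   shrinkage, in \[0, 1\]. The default 1 uses the trended dispersion for
#'   every gene -- the standard choice at pseudobulk sample sizes (a few
#'   tumors per arm), where gene-wise estimates are too noisy and leave
#'   the Wald test's extreme tail anticonservative. Lower values blend in
#'   the gene-wise Cox-Reid estimates.
#' @return A `de_result`: list with `table` (tibble: gene_id, base_mean,
#'   log2fc, lfc_se, stat, pvalue, qvalue), `size_factors`, `dispersions`,
#'   `levels`.
#' @export
nb_wald_de <- function(counts, condition, prior_weight = 1) {
  if (inherits(counts, "pseudobulk")) counts <- counts$counts
  counts <- as.matrix(counts)
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly 2 levels")
  if (any(table(condition) < 2)) stop("need >= 2 tumors per condition")
  if (prior_weight < 0 || prior_weight > 1) stop("prior_weight must be in [0, 1]")

  nz <- rowSums(counts) > 0
  n_zero <- sum(!nz)
  counts <- counts[nz, , drop = FALSE]
  x <- as.numeric(condition == levels(condition)[2])

  sf <- size_factors_mor(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  ## initial dispersion: method of moments on normalized counts
  v <- apply(norm, 1, stats::var)
  phi0 <- pmin(pmax((v - base_mean * mean(1 / sf)) / base_mean^2, 1e-8), 10)

  fit0 <- nb_glm_two_group(counts, sf, x, phi0)
  ## gene-wise CR-APL dispersion, means fixed at the working fit
  phi_gene <- vapply(seq_len(nrow(counts)), function(g) {
    opt <- stats::optimize(function(lp) {
      -nb_apl(exp(lp), counts[g, ], fit0$mu[g, ], x)
    }, interval = c(log(1e-8), log(30)), tol = 1e-6)
    exp(opt$minimum)
  }, numeric(1))

  ## parametric trend a0 + a1/mean, fitted robustly on log scale
  trend_df <- data.frame(phi = phi_gene, inv_mu = 1 / base_mean)
  use <- phi_gene > 1e-6 & phi_gene < 20
  a <- c(stats::median(phi_gene[use]), 0)
  for (it in 1:4) {
    pred <- pmax(a[1] + a[2] * trend_df$inv_mu, 1e-8)
    resid <- log(trend_df$phi) - log(pred)
    keep <- use & abs(resid - stats::median(resid[use])) < 2 * stats::mad(resid[use])
    trend_df$w <- 1 / pred^2
    fit_lm <- stats::lm(phi ~ inv_mu, data = trend_df[keep, ],
                        weights = trend_df$w[keep])
    a <- pmax(stats::coef(fit_lm), c(1e-8, 0))
  }
  phi_trend <- pmax(a[1] + a[2] / base_mean, 1e-8)

  log_phi <- (1 - prior_weight) * log(pmax(phi_gene, 1e-8)) +
    prior_weight * log(phi_trend)
  phi_final <- exp(log_phi)

  fit <- nb_glm_two_group(counts, sf, x, phi_final)
  log2fc <- fit$b1 / log(2)
  lfc_se <- fit$se_b1 / log(2)
  stat <- fit$b1 / fit$se_b1
  pvalue <- 2 * stats::pnorm(-abs(stat))
  tab <- tibble::tibble(gene_id = rownames(counts),
                        base_mean = base_mean,
                        log2fc = log2fc,
                        lfc_se = lfc_se,
                        stat = stat,
                        pvalue = pvalue,
                        qvalue = bh_fdr(pvalue))
  out <- structure(list(table = tab,
                        size_factors = sf,
                        dispersions = stats::setNames(phi_final,
                                                      rownames(counts)),
                        levels = levels(condition)),
                   class = "de_result")
  attr(out, "n_zero_genes") <- n_zero
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", nrow(x$table), " genes; contrast ", x$levels[2], " vs ",
      x$levels[1], "; ", sum(x$table$qvalue < 0.05, na.rm = TRUE),
      " genes at q < 0.05\n", sep = "")
  invisible(x)
}

#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$table

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table),
                 n_sig_q05 = sum(x$table$qvalue < 0.05, na.rm = TRUE),
                 median_dispersion = stats::median(x$dispersions, na.rm = TRUE))
}

#' Random-intercept linear mixed model for AOI-level responses
#'
#' REML fit of `response ~ group + (1 | patient)`: the group structure
#' (e.g. treatment arm x tumor setting) enters as a fixed effect and
#' patient as a random intercept, accounting for repeated tumors/AOIs per
#' patient. Falls back to ordinary least squares with a warning when the
#' mixed fit fails.
#'
#' @param data Data frame with the response, group and patient columns.
#' @param response,group,patient Column names (strings).
#' @return An `ri_fit`: list with the fitted model (`fit`), the column
#'   names, and `method` ("lmm" or "ols").
#' @export
fit_random_intercept <- function(data, response = "y", group = "group",
                                 patient = "patient") {
  data <- as.data.frame(data)
  for (col in c(response, group, patient)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  if (length(unique(data[[patient]])) < 2) stop("need >= 2 patients")
  data[[group]] <- factor(data[[group]])
  data[[patient]] <- factor(data[[patient]])
  fml <- stats::as.formula(paste0(response, " ~ ", group, " + (1 | ", patient, ")"))
  fit <- tryCatch(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12))),
    error = function(e) NULL)
  method <- "lmm"
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to OLS")
    fit <- stats::lm(stats::as.formula(paste0(response, " ~ ", group)),
                     data = data)
    method <- "ols"
  }
  structure(list(fit = fit, response = response, group = group,
                 patient = patient, data = data, method = method),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("<ri_fit> ", x$response, " ~ ", x$group, " + (1 | ", x$patient, ") [",
      x$method, "]\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' @method tidy ri_fit
#' @export
tidy.ri_fit <- function(x, ...) {
  if (x$method == "lmm") {
    co <- as.data.frame(stats::coef(summary(x$fit)))
    tibble::tibble(term = rownames(co),
                   estimate = co[["Estimate"]],
                   std_error = co[["Std. Error"]],
                   df = co[["df"]],
                   statistic = co[["t value"]],
                   p_value = co[["Pr(>|t|)"]])
  } else {
    co <- as.data.frame(stats::coef(summary(x$fit)))
    tibble::tibble(term = rownames(co),
                   estimate = co[["Estimate"]],
                   std_error = co[["Std. Error"]],
                   df = stats::df.residual(x$fit),
                   statistic = co[["t value"]],
                   p_value = co[["Pr(>|t|)"]])
  }
}

#' @method glance ri_fit
#' @export
glance.ri_fit <- function(x, ...) {
  if (x$method == "lmm") {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    tibble::tibble(var_patient = vc$vcov[vc$grp == x$patient],
                   var_residual = vc$vcov[vc$grp == "Residual"],
                   reml_criterion = as.numeric(lme4::REMLcrit(x$fit)),
                   n_obs = stats::nobs(x$fit),
                   n_patients = lme4::ngrps(x$fit)[[x$patient]])
  } else {
    tibble::tibble(var_patient = 0,
                   var_residual = summary(x$fit)$sigma^2,
                   reml_criterion = NA_real_,
                   n_obs = stats::nobs(x$fit),
                   n_patients = length(unique(x$data[[x$patient]])))
  }
}

#' Estimated marginal means with Tukey-adjusted pairwise contrasts
#'
#' Model-based cell means for every group of an [fit_random_intercept()]
#' fit, with all pairwise contrasts adjusted by the studentized-range
#' (Tukey) method. Satterthwaite denominator degrees of freedom are used
#' for mixed fits. With two groups the Tukey adjustment reduces to the
#' unadjusted t test.
#'
#' @param x An `ri_fit`.
#' @return List of class `emm_result`: `emmeans` (tibble: group, emmean,
#'   se, df, lower_cl, upper_cl) and `contrasts` (tibble: contrast,
#'   estimate, se, df, t_ratio, p_value).
#' @export
emmeans_tukey <- function(x) {
  stopifnot(inherits(x, "ri_fit"))
  em <- emmeans::emmeans(x$fit, specs = x$group, lmer.df = "satterthwaite")
  ctr <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  emt <- as.data.frame(em)
  ctt <- as.data.frame(ctr)
  structure(list(
    emmeans = tibble::tibble(group = as.character(emt[[1]]),
                             emmean = emt$emmean, se = emt$SE, df = emt$df,
                             lower_cl = emt$lower.CL, upper_cl = emt$upper.CL),
    contrasts = tibble::tibble(contrast = as.character(ctt$contrast),
                               estimate = ctt$estimate, se = ctt$SE,
                               df = ctt$df, t_ratio = ctt$t.ratio,
                               p_value = ctt$p.value)),
    class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat("<emm_result>\n")
  print(x$emmeans)
  print(x$contrasts)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (step-up with monotonicity enforcement).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped
#' (Wilcoxon convention) and ties receive midranks. For n <= `exact_max`
#' the p-value is exact, from the null distribution of the signed-rank
#' statistic over all 2^n sign assignments (computed by a shift algorithm
#' over doubled midranks, so ties are handled exactly); larger samples use
#' the normal approximation with tie correction.
#'
#' @param x Numeric vector: differences, or first members of pairs if `y`
#'   given.
#' @param y Optional second members of pairs.
#' @param exact_max Largest n for exact enumeration (default 25).
#' @return List: `statistic` (W, sum of positive ranks), `p_value`, `n`
#'   (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    total <- sum(r2)
    f <- numeric(total + 1)               # f[w+1] = #assignments with W2 = w
    f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1):(total + 1)] <- g[(rr + 1):(total + 1)] + f[1:(total + 1 - rr)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE)$p.value)
    method <- "normal_approximation"
  }
  list(statistic = unname(w), p_value = p, n = n, method = method)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided unpaired rank-sum test: exact when the combined sample size is
#' at most `exact_max` and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest combined size for the exact distribution.
#' @return List: `statistic` (Mann-Whitney U), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = !use_exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "exact" else "normal_approximation")
}
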