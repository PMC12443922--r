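# Shared fixtures: cohorts are expensive, so they are generated once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# small cohort for structural/IO tests (fast, no preprocessing)
small_cohort <- function() cached_fixture("small", function() {
  simulate_cohort(sim_config(n_patients = 6, n_genes = 600, cnv_window = 40,
                             seed = 7))
})

# default-condition cohort, fully preprocessed; used by purity-filter and
# signature tests
default_cohort <- function() cached_fixture("default", function() {
  sim <- simulate_cohort(sim_config(seed = 1))
  pre <- suppressWarnings(preprocess_dataset(sim$dataset))
  meta <- sim$dataset$aoi_meta
  list(sim = sim, pre = pre,
       sox2 = meta$aoi_id[meta$segment == "SOX2"],
       iba1 = meta$aoi_id[meta$segment == "IBA1"])
})

# hallmark-recovery cohort: altered AOIs at purity >= 0.6, plus purity-0 AOIs
cnv_cohort <- function() cached_fixture("cnv", function() {
  sim <- simulate_cohort(sim_config(purity_grid = c(0, 0.6, 0.8, 1), seed = 1))
  pre <- suppressWarnings(preprocess_dataset(sim$dataset))
  meta <- sim$dataset$aoi_meta
  list(sim = sim, pre = pre,
       sox2 = meta$aoi_id[meta$segment == "SOX2"],
       iba1 = meta$aoi_id[meta$segment == "IBA1"])
})

# a normalized_matrix directly from numbers (bypasses counts), for unit tests
as_norm <- function(m) {
  structure(m, normalized = TRUE, batch_corrected = FALSE,
            class = c("normalized_matrix", "matrix", "array"))
}
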