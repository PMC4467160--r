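# Shared fixtures: a small simulated study and its integrated form, built
# once per test run.

small_config <- function(seed = 101L, ...) {
  sim_config(n_datasets = 2L, samples_per_dataset = 150L, n_genes = 120L,
             n_signature_genes = 30L, seed = seed, ...)
}

# normalize -> collapse -> subtype per dataset -> standardize -> pool
integrate_sim <- function(sim) {
  cohorts <- lapply(sim$cohorts, function(co) {
    co$matrix <- quantile_normalize(co$matrix)
    collapse_probes(co)
  })
  labels <- c()
  cohorts <- lapply(cohorts, function(co) {
    tum <- names(co$sample_roles)[co$sample_roles == "tumor"]
    l <- assign_subtypes(co$matrix[, tum, drop = FALSE], sim$centroids)
    labels <<- c(labels, l)
    suppressWarnings(standardize_to_reference(co, l, "LumA"))
  })
  list(pooled = pool_cohorts(cohorts), labels = labels)
}

# medium-sized integrated study, cached across test files
get_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_datasets = 3L, samples_per_dataset = 300L,
                        n_genes = 500L, n_signature_genes = 60L, seed = 42L)
      sim <- generate_cohorts(cfg)
      int <- integrate_sim(sim)
      clinical <- call_all_markers(int$pooled, sim$clinical)
      clinical$subtype <- unname(int$labels[clinical$sample_id])
      cache <<- list(cfg = cfg, sim = sim, pooled = int$pooled,
                     labels = int$labels, clinical = clinical)
    }
    cache
  }
})
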