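test_that("configuration invariants are enforced", {
  expect_error(sim_config(subtype_proportions = c(LumA = 0.5, LumB = 0.5,
                                                  Basal = 0, ERBB2 = 0.1,
                                                  NormalLike = 0)),
               "sum to 1")
  expect_error(sim_config(n_datasets = 0), "at least one dataset")
  expect_error(sim_config(samples_per_dataset = -3), "non-negative")
  expect_error(sim_config(pdl1_up_prevalence = c(LumA = 1.2, LumB = 0.1,
                                                 Basal = 0.3, ERBB2 = 0.2,
                                                 NormalLike = 0.1)),
               "fractions")
  expect_error(sim_config(hr_mfs = c(LumA = 1, LumB = 1, Basal = -0.5,
                                     ERBB2 = 1, NormalLike = 1)),
               "positive")
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- small_config(seed = 7L)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a$cohorts[[1]]$matrix, b$cohorts[[1]]$matrix)
  expect_identical(a$cohorts[[2]]$matrix, b$cohorts[[2]]$matrix)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_cna(cfg, a$truth), generate_cna(cfg, b$truth))
})

test_that("true PDL1-up prevalence in basal tumors matches the configured 38%", {
  cfg <- sim_config(n_datasets = 1L, samples_per_dataset = 10000L,
                    n_genes = 40L, n_signature_genes = 10L,
                    n_normal_per_dataset = 2L,
                    subtype_proportions = c(LumA = 0, LumB = 0, Basal = 1,
                                            ERBB2 = 0, NormalLike = 0),
                    seed = 11L)
  sim <- generate_cohorts(cfg)
  p_hat <- mean(sim$truth$samples$pdl1_up)
  tol <- 3 * sqrt(0.38 * 0.62 / 10000)
  expect_lt(abs(p_hat - 0.38), tol)
})

test_that("subtype frequencies obey the law of large numbers", {
  cfg <- sim_config(n_datasets = 1L, samples_per_dataset = 10000L,
                    n_genes = 40L, n_signature_genes = 10L,
                    n_normal_per_dataset = 2L, seed = 13L)
  sim <- generate_cohorts(cfg)
  freq <- table(sim$truth$samples$subtype) / 10000
  for (s in names(cfg$subtype_proportions)) {
    p <- cfg$subtype_proportions[[s]]
    expect_lt(abs(freq[[s]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("log-rank p-values are uniform when the up-group hazard is null", {
  hr_null <- c(LumA = 1, LumB = 1, Basal = 1, ERBB2 = 1, NormalLike = 1)
  pvals <- vapply(seq_len(200), function(i) {
    cfg <- sim_config(n_datasets = 1L, samples_per_dataset = 150L,
                      n_genes = 40L, n_signature_genes = 10L,
                      n_normal_per_dataset = 0L,
                      hr_mfs = hr_null, seed = 5000L + i)
    cl <- generate_cohorts(cfg)
    tr <- cl$truth$samples
    clin <- cl$clinical
    logrank_test(clin$mfs_time, clin$mfs_event,
                 ifelse(tr$pdl1_up, "up", "no_up"))$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("copy-number table respects the configured gain structure", {
  # all gain probabilities zero: everything neutral
  cfg0 <- small_config(cna_gain_prob = c(LumA = 0, LumB = 0, Basal = 0,
                                         ERBB2 = 0, NormalLike = 0))
  sim0 <- generate_cohorts(cfg0)
  cna0 <- generate_cna(cfg0, sim0$truth)
  expect_true(all(call_cna(cna0$log2_ratio) == "neutral"))

  # basal-enriched gains at the configured rates
  cfg <- sim_config(n_datasets = 1L, samples_per_dataset = 6000L,
                    n_genes = 40L, n_signature_genes = 10L,
                    n_normal_per_dataset = 0L, seed = 17L)
  sim <- generate_cohorts(cfg)
  cna <- generate_cna(cfg, sim$truth)
  st <- call_cna(cna$log2_ratio)
  gained <- st %in% c("gain", "amplification")
  tr <- sim$truth$samples
  for (s in c("Basal", "LumA")) {
    idx <- tr$subtype == s
    p <- cfg$cna_gain_prob[[s]]
    expect_lt(abs(mean(gained[idx]) - p),
              3 * sqrt(p * (1 - p) / sum(idx)))
  }
  # gained ratios sit at or above the 1.5x threshold
  expect_true(all(cna$log2_ratio[tr$cna_gain] >= log2(1.5)))
})

test_that("gained samples carry higher PDL1 expression by construction", {
  cfg <- sim_config(n_datasets = 1L, samples_per_dataset = 1200L,
                    n_genes = 40L, n_signature_genes = 10L,
                    n_normal_per_dataset = 0L, seed = 19L)
  sim <- generate_cohorts(cfg)
  tr <- sim$truth$samples
  expr <- sim$cohorts[[1]]$matrix["CD274_1", tr$sample_id]
  tt <- stats::t.test(expr[tr$cna_gain], expr[!tr$cna_gain],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("a simulated study round-trips through the plain-text writers", {
  cfg <- small_config()
  sim <- generate_cohorts(cfg)
  cna <- generate_cna(cfg, sim$truth)
  dir <- withr::local_tempdir()
  write_simulation(sim, cfg, dir, cna = cna)
  m <- read_expression_tsv(file.path(dir, "expression_DS01.tsv"))
  expect_equal(m, sim$cohorts[[1]]$matrix)
  cl <- read_clinical_csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(cl), nrow(sim$clinical))
  ce <- read_centroids_tsv(file.path(dir, "centroids.tsv"))
  expect_equal(ce, sim$centroids)
})
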