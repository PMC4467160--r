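test_that("quantile normalization matches the hand-computed example", {
  m <- matrix(c(1, 3, 4, 2), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out),
               matrix(c(1.5, 3.5, 3.5, 1.5), nrow = 2))
  expect_identical(dimnames(out), dimnames(m))
})

test_that("quantile normalization fixed points and error handling", {
  const <- matrix(5, nrow = 4, ncol = 3,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(quantile_normalize(const), const)

  set.seed(1)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  q1 <- quantile_normalize(m)
  # identical column distributions and idempotence
  sorted <- apply(q1, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_lt(max(abs(colSums(q1) - colSums(q1)[1])), 1e-9)
  expect_lt(max(abs(quantile_normalize(q1) - q1)), 1e-12)

  m[3, 2] <- NA
  expect_error(quantile_normalize(m), "missing")
  one <- matrix(1:4, ncol = 1, dimnames = list(paste0("g", 1:4), "s1"))
  expect_warning(out1 <- quantile_normalize(one), "single column")
  expect_equal(unname(out1), unname(one))
})

make_probe_cohort <- function(mat, map) {
  expression_cohort("D1", "test", mat, probe_map = map)
}

test_that("probe collapse keeps the highest-variance probe per gene", {
  mat <- rbind(p1 = c(0, 2, 4, 6),    # var 20/3, gene G1
               p2 = c(1, 2, 3, 4),    # var 5/3,  gene G1
               p3 = c(5, 5, 6, 6),    # gene G2, single probe
               px = c(9, 9, 9, 9))    # unmapped, dropped
  colnames(mat) <- paste0("s", 1:4)
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("G1", "G1", "G2"))
  out <- collapse_probes(make_probe_cohort(mat, map))
  expect_equal(sort(rownames(out$matrix)), c("G1", "G2"))
  expect_equal(unname(out$matrix["G1", ]), c(0, 2, 4, 6))
  # gene count equals distinct mapped genes
  expect_equal(nrow(out$matrix), length(unique(map$gene_id)))
})

test_that("probe collapse breaks exact variance ties lexicographically", {
  mat <- rbind(pb = c(1, 2, 3, 4), pa = c(2, 3, 4, 5))  # equal variance
  colnames(mat) <- paste0("s", 1:4)
  map <- data.frame(probe_id = c("pb", "pa"), gene_id = c("G1", "G1"))
  out <- collapse_probes(make_probe_cohort(mat, map))
  expect_equal(unname(out$matrix["G1", ]), c(2, 3, 4, 5))  # "pa" < "pb"
  expect_error(collapse_probes(make_probe_cohort(mat, map[0, ])), "empty")
})

test_that("standardization anchors the reference subpopulation at mean 0, SD 1", {
  set.seed(2)
  mat <- matrix(rnorm(50 * 60, 7, 1.3), 50, 60,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:60)))
  mat["g50", ] <- 4  # constant gene
  labs <- rep(c("LumA", "Basal", "LumB"), each = 20)
  names(labs) <- colnames(mat)
  co <- expression_cohort("D1", "test", mat)
  std <- standardize_to_reference(co, labs, "LumA")
  ref <- names(labs)[labs == "LumA"]
  mu <- rowMeans(std$matrix[1:49, ref])
  sd <- apply(std$matrix[1:49, ref], 1, sd)
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(sd - 1)), 1e-9)
  expect_true("g50" %in% attr(std, "floored_genes"))
  # ranks preserved per gene (monotone affine map)
  expect_equal(apply(std$matrix[1:10, ], 1, rank),
               apply(mat[1:10, ], 1, rank))
  expect_error(standardize_to_reference(co, labs, "NotASubtype"), "unknown")
})

test_that("standardization falls back to the whole dataset when the reference is absent", {
  set.seed(3)
  mat <- matrix(rnorm(20 * 30, 5, 1), 20, 30,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  labs <- rep("Basal", 30)
  names(labs) <- colnames(mat)
  co <- expression_cohort("D1", "test", mat)
  expect_warning(std <- standardize_to_reference(co, labs, "LumA"),
                 "falling back")
  expect_true(attr(std, "fallback"))
  expect_lt(max(abs(rowMeans(std$matrix))), 1e-9)
})

test_that("luminal-A referencing removes a two-unit location batch effect", {
  # two large cohorts with opposite location shifts and a shared composition
  set.seed(4)
  n <- 20000; genes <- paste0("g", 1:20)
  labs_all <- c()
  cohorts <- lapply(1:2, function(d) {
    shift <- c(2, -2)[d]
    ids <- sprintf("D%d_s%05d", d, 1:n)
    mat <- matrix(rnorm(20 * n, 7, 1), 20, n,
                  dimnames = list(genes, ids)) + shift
    labs <- sample(c("LumA", "Basal", "LumB"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
    names(labs) <- ids
    labs_all <<- c(labs_all, labs)
    standardize_to_reference(expression_cohort(paste0("D", d), "t", mat),
                             labs, "LumA")
  })
  pooled <- pool_cohorts(cohorts)
  d1 <- pooled$provenance$dataset_id == "D1"
  diff <- rowMeans(pooled$matrix[, d1]) - rowMeans(pooled$matrix[, !d1])
  expect_lt(max(abs(diff)), 0.05)
})

test_that("PCA silhouette by dataset drops after standardization while subtype structure persists", {
  cfg <- sim_config(n_datasets = 3L, samples_per_dataset = 80L,
                    n_genes = 120L, n_signature_genes = 30L,
                    batch_location_sd = 1.5, seed = 23L)
  sim <- generate_cohorts(cfg)
  tr <- sim$truth$samples
  collapsed <- lapply(sim$cohorts, function(co) {
    co$matrix <- quantile_normalize(co$matrix)
    collapse_probes(co)
  })
  before <- pool_cohorts(collapsed)
  std <- lapply(collapsed, function(co) {
    tum <- names(co$sample_roles)[co$sample_roles == "tumor"]
    labs <- assign_subtypes(co$matrix[, tum, drop = FALSE], sim$centroids)
    suppressWarnings(standardize_to_reference(co, labs, "LumA"))
  })
  after <- pool_cohorts(std)
  panel <- rownames(sim$centroids)
  tum_ids <- tr$sample_id
  subt <- tr$subtype
  ds <- tr$dataset_id
  chk_before <- pca_batch_check(before$matrix[, tum_ids], ds, subt, panel)
  chk_after <- pca_batch_check(after$matrix[, tum_ids], ds, subt, panel)
  expect_lt(chk_after$silhouette_dataset, chk_before$silhouette_dataset)
  expect_gt(chk_after$silhouette_group, chk_after$silhouette_dataset)
})
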