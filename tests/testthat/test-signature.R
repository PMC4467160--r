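test_that("moderated t matches an independently coded oracle to 1e-8", {
  set.seed(30)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  m[7, 4:6] <- m[7, 4:6] + 4   # one strong effect
  labels <- rep(c("no_up", "up"), each = 3)
  res <- moderated_t(m, factor(labels, levels = c("no_up", "up")))
  ora <- oracle_moderated_t(m, labels == "up")
  expect_equal(res$t, ora$t, tolerance = 1e-8)
  expect_equal(res$p, ora$p, tolerance = 1e-8)
  expect_equal(res$q, ora$q, tolerance = 1e-8)
  expect_equal(attr(res, "d0"), ora$d0, tolerance = 1e-6)
  # the planted gene ranks first
  expect_equal(which.max(abs(res$t)), 7L)
})

test_that("zero prior degrees of freedom recovers the ordinary pooled t", {
  set.seed(31)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  labels <- rep(c("a", "b"), each = 5)
  res <- moderated_t(m, labels, prior_df = 0)
  for (g in c(1, 9, 30)) {
    tt <- t.test(m[g, 6:10], m[g, 1:5], var.equal = TRUE)
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("shrinkage is a no-op when all genes share one sample variance", {
  # each gene is the same centered pattern plus a gene-specific mean shift,
  # so every pooled variance is identical
  base1 <- c(-1, 0, 1, -2, 2); base2 <- c(0.5, -0.5, 1.5, -1.5, 0)
  m <- t(vapply(1:20, function(g) c(base1 + g, base2 + 2 * g),
                numeric(10)))
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:10))
  labels <- rep(c("a", "b"), each = 5)
  res <- moderated_t(m, labels)
  expect_equal(res$s2_post, res$s2, tolerance = 1e-9)
})

test_that("moderated-t p-values are uniform under the global null", {
  set.seed(32)
  m <- matrix(rnorm(2000 * 12), 2000, 12,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:12)))
  res <- moderated_t(m, rep(c("a", "b"), each = 6))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("moderated t agrees with the established empirical Bayes implementation", {
  set.seed(33)
  m <- matrix(rnorm(200 * 8, sd = rep(runif(200, 0.5, 2), 8)), 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  labels <- rep(c("a", "b"), each = 4)
  res <- moderated_t(m, labels)
  design <- cbind(1, labels == "b")
  eb <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(res$t, eb$t[, 2]), 0.9999)
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 0.05 * eb$df.prior)
})

test_that("signature selection enforces all three thresholds", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.5, 0.9, -1.2, 1.4),
                   t = c(5, 4.5, -4, 0.5),
                   p = c(0.001, 0.04, 0.002, 0.06),
                   q = c(0.01, 0.04, 0.01, 0.2))
  sel <- select_signature(de)
  expect_equal(sel$up$gene_id, "a")          # b fails |FC|, d fails p/q
  expect_equal(sel$down$gene_id, "c")

  # under the global null the selection is empty in almost all repeats
  empty <- 0
  for (i in 1:20) {
    set.seed(5000 + i)
    m <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
    res <- moderated_t(m, rep(c("a", "b"), each = 5))
    sel0 <- select_signature(res)
    empty <- empty + (nrow(sel0$up) + nrow(sel0$down) == 0)
  }
  expect_gte(empty, 18)
})

test_that("simulated signature genes are recovered with high recall and low FDR", {
  fx <- get_fixture()
  tr_genes <- fx$sim$truth$genes
  tumors <- fx$clinical[fx$clinical$role == "tumor", ]
  learn <- tumors$sample_id[tumors$dataset_id == "DS01"]
  truth_up <- fx$sim$truth$samples$pdl1_up[
    match(learn, fx$sim$truth$samples$sample_id)]
  de <- moderated_t(fx$pooled$matrix[, learn],
                    factor(ifelse(truth_up, "up", "no_up"),
                           levels = c("no_up", "up")))
  sel <- select_signature(de)
  called <- c(sel$up$gene_id, sel$down$gene_id)
  true_de <- tr_genes$gene_id[tr_genes$class %in%
                                c("signature_up", "signature_down")]
  recall <- mean(true_de %in% called)
  expect_gte(recall, 0.9)
  # false discoveries are calls on pure-noise genes; marker and subtype
  # panel genes are genuinely group-associated through the subtype
  # composition (as hormone-pathway genes are in the real contrast)
  noise <- tr_genes$gene_id[tr_genes$class == "filler"]
  fdr <- sum(called %in% noise) / length(called)
  expect_lte(fdr, 0.1)
})

test_that("metagene threshold splits separable scores and shifts with the data", {
  m <- matrix(c(0, 1, 2, 3), nrow = 1,
              dimnames = list("gA", paste0("s", 1:4)))
  labels <- c("no_up", "no_up", "up", "up")
  fit <- fit_metagene(m, "gA", labels)
  expect_equal(fit$threshold, 1.5)
  expect_equal(fit$train_accuracy, 1)
  expect_equal(fit$auc, 1)
  # adding a constant shifts the threshold by the same constant
  fit2 <- fit_metagene(m + 10, "gA", labels)
  expect_equal(fit2$threshold, fit$threshold + 10)
  expect_error(fit_metagene(m * 0, "gA", labels), "constant")

  # permuted labels: Youden J near zero on average
  set.seed(34)
  mm <- matrix(rnorm(200), nrow = 1,
               dimnames = list("gA", paste0("s", 1:200)))
  js <- vapply(1:20, function(i) {
    fit_metagene(mm, "gA", sample(rep(c("up", "no_up"), 100)))$youden
  }, numeric(1))
  expect_lt(mean(js), 0.3)
})

test_that("validation on the learning set reproduces the training accuracy", {
  fx <- get_fixture()
  tumors <- fx$clinical[fx$clinical$role == "tumor", ]
  learn <- tumors$sample_id[tumors$dataset_id == "DS01"]
  lab <- tumors$pdl1[match(learn, tumors$sample_id)]
  sel <- select_signature(
    moderated_t(fx$pooled$matrix[, learn],
                factor(lab, levels = c("no_up", "up"))))
  model <- fit_metagene(fx$pooled$matrix[, learn], sel$up$gene_id, lab)
  self <- validate_metagene(model, fx$pooled$matrix[, learn], lab)
  expect_equal(self$accuracy, model$train_accuracy)
  expect_equal(self$coverage, 1)
})
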