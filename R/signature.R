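# Supervised differential expression between PDL1 groups with an empirical
# Bayes moderated t-test, signature selection (p < 5%, q < 5%, |FC| > 2x),
# metagene construction (mean expression of the upregulated genes) with a
# ROC-derived threshold, and held-out validation.

# Newton inversion of the trigamma function (used for the moment-matching
# estimate of the prior degrees of freedom)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Moderated two-sample t-test
#'
#' Per-gene pooled variances are shrunk toward an ensemble prior:
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, with the hyperparameters
#' `(d0, s0^2)` estimated by moment matching on `log(s2)` (trigamma
#' inversion). The moderated statistic `t = dmean / (s_tilde *
#' sqrt(1/n1 + 1/n2))` is referred to a t distribution on `d0 + d` degrees
#' of freedom; q-values are Benjamini-Hochberg.
#'
#' @param m genes x samples matrix (log2 scale).
#' @param labels two-level grouping; differences are `test - reference`
#'   means, where `reference` is the first factor level.
#' @param prior_df optional override of the prior degrees of freedom `d0`
#'   (0 recovers the ordinary pooled t-test, Inf full shrinkage).
#' @return data frame with one row per gene: `gene_id`, `log2fc`, `t`,
#'   `df`, `p`, `q`, `s2`, `s2_post`; attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(m, labels, prior_df = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("moderated_t: labels must have exactly two levels")
  labels <- droplevels(labels)
  i1 <- which(labels == levels(labels)[1])  # reference
  i2 <- which(labels == levels(labels)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("moderated_t: need at least 2 samples per group")
  if (nrow(m) < 10L)
    stop("moderated_t: need at least 10 genes for variance shrinkage")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (all(s2 < 1e-300))
    stop("moderated_t: zero within-group variance for all genes")

  if (is.null(prior_df)) {
    ok <- s2 > 1e-300
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    G <- length(e)
    rhs <- mean((e - mean(e))^2 * G / (G - 1) - trigamma(d / 2))
    if (rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess variance in log s2: fully shrink to the common variance
      d0 <- Inf
      s0_2 <- exp(mean(z))
    }
  } else {
    d0 <- prior_df
    s0_2 <- if (d0 > 0) exp(mean(log(s2[s2 > 1e-300]))) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + d * s2) / (d0 + d)
  fc <- m2 - m1
  tt <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_tot <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_tot)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(m), log2fc = fc, t = tt,
                    df = df_tot, p = p, q = q, s2 = s2, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Select the differential-expression signature
#'
#' Applies the three significance thresholds — raw p below `p_max`, BH q
#' below `q_max`, and absolute fold change of at least `fc_min` on the
#' linear scale (|log2 FC| >= log2(fc_min)) — and splits the surviving genes
#' by direction, ordered by decreasing |t|.
#'
#' @param de result of [moderated_t()].
#' @param p_max,q_max,fc_min thresholds (defaults 0.05, 0.05, 2).
#' @return list with data frames `up` and `down` (same columns as `de` plus
#'   `direction`).
#' @export
select_signature <- function(de, p_max = 0.05, q_max = 0.05, fc_min = 2) {
  lfc <- log2(fc_min)
  sel <- de[!is.na(de$p) & de$p < p_max & de$q < q_max &
              abs(de$log2fc) >= lfc, , drop = FALSE]
  sel <- sel[order(-abs(sel$t)), , drop = FALSE]
  sel$direction <- ifelse(sel$log2fc > 0, "up", "down")
  list(up = sel[sel$direction == "up", , drop = FALSE],
       down = sel[sel$direction == "down", , drop = FALSE])
}

metagene_score <- function(m, up_genes) {
  genes <- intersect(up_genes, rownames(m))
  if (length(genes) == 0L)
    stop("metagene: none of the signature genes are present in the matrix")
  colMeans(m[genes, , drop = FALSE])
}

#' Fit a metagene classifier on a learning set
#'
#' The metagene score of a sample is the arithmetic mean of its upregulated
#' signature genes. The classification threshold is the midpoint between
#' adjacent distinct scores that maximizes Youden's J (sensitivity +
#' specificity - 1) on the learning set; ties take the lowest threshold.
#'
#' @param m genes x samples learning matrix.
#' @param up_genes character vector of upregulated signature genes.
#' @param labels true binary status per sample; the positive class is
#'   `positive_level`.
#' @param positive_level label value treated as positive (default `"up"`).
#' @return object of class `metagene_model`: list with `up_genes`,
#'   `threshold`, `youden`, `auc`, `train_accuracy`.
#' @export
fit_metagene <- function(m, up_genes, labels, positive_level = "up") {
  score <- metagene_score(m, up_genes)
  y <- as.character(labels) == positive_level
  if (length(unique(score)) < 2L)
    stop("fit_metagene: scores are constant, no threshold exists")
  s <- sort(unique(score))
  cand <- (s[-1] + s[-length(s)]) / 2
  jay <- vapply(cand, function(th) {
    pred <- score >= th
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    sens + spec - 1
  }, numeric(1))
  threshold <- cand[which.max(jay)]   # first max = lowest threshold
  # rank-based AUC (Mann-Whitney)
  r <- rank(score)
  auc <- (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  pred <- score >= threshold
  structure(list(up_genes = intersect(up_genes, rownames(m)),
                 threshold = threshold, youden = max(jay), auc = auc,
                 train_accuracy = mean(pred == y),
                 positive_level = positive_level),
            class = "metagene_model")
}

#' @export
print.metagene_model <- function(x, ...) {
  cat(sprintf("Metagene classifier: %d genes, threshold %.3f (Youden J %.2f, AUC %.3f, training accuracy %.1f%%)\n",
              length(x$up_genes), x$threshold, x$youden, x$auc,
              100 * x$train_accuracy))
  invisible(x)
}

#' @export
predict.metagene_model <- function(object, newdata, ...) {
  score <- metagene_score(newdata, object$up_genes)
  status <- ifelse(score >= object$threshold, object$positive_level,
                   paste0("no_", object$positive_level))
  data.frame(sample_id = colnames(newdata), score = score,
             predicted = status, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Validate a metagene classifier on an independent cohort
#'
#' Scores the validation samples, predicts status at the learned threshold,
#' and reports the accuracy, the confusion table, and the two-sided Fisher
#' exact p-value of the predicted-versus-observed association. A warning is
#' issued when fewer than 80% of signature genes are measured in the
#' validation matrix.
#'
#' @param model a [fit_metagene()] result.
#' @param m genes x samples validation matrix (disjoint from learning).
#' @param labels observed binary status per validation sample.
#' @return list with `accuracy`, `p`, `confusion`, `coverage`.
#' @export
validate_metagene <- function(model, m, labels) {
  genes <- intersect(model$up_genes, rownames(m))
  coverage <- length(genes) / length(model$up_genes)
  if (coverage < 0.8)
    warning(sprintf("validate_metagene: only %.0f%% of signature genes measured",
                    100 * coverage))
  pred <- predict(model, m)
  y <- as.character(labels) == model$positive_level
  yhat <- pred$predicted == model$positive_level
  confusion <- table(predicted = factor(yhat, levels = c(FALSE, TRUE)),
                     observed = factor(y, levels = c(FALSE, TRUE)))
  p <- fisher_exact(unclass(confusion))
  list(accuracy = mean(yhat == y), p = p, confusion = confusion,
       coverage = coverage)
}
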