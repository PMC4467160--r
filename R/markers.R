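# Marker dichotomization: ER/PR/ERBB2/Ki67 by a bimodal Gaussian-mixture
# cutoff per dataset, PDL1 by the tumor / normal-breast expression ratio
# (upregulated iff the ratio is at least 2, i.e. a log2 difference >= 1).

#' Bimodal expression cutoff from a two-component Gaussian mixture
#'
#' Fits an equal-variance two-component Gaussian mixture by EM (deterministic
#' model-based initialization) and returns the point between the two
#' component means at which posterior membership is 0.5. If the fitted means
#' are separated by less than half the pooled SD the distribution is flagged
#' as not bimodal and the sample median is returned instead.
#'
#' @param values numeric log2 expression vector, n >= 20.
#' @return list with `cutoff`, `bimodal` flag, component `means`, common
#'   `sd`, and mixing `weights`.
#' @importFrom mclust Mclust mclustBIC
#' @export
bimodal_cutoff <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 20L)
    stop("bimodal_cutoff: need at least 20 finite values")
  if (stats::sd(values) < 1e-12)
    stop("bimodal_cutoff: constant vector")
  # Mclust resolves mclustBIC in the calling frame, hence the explicit import
  fit <- tryCatch(
    Mclust(values, G = 2, modelNames = "E", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(cutoff = stats::median(values), bimodal = FALSE,
                means = rep(mean(values), 2), sd = stats::sd(values),
                weights = c(0.5, 0.5)))
  }
  p <- fit$parameters
  mns <- as.numeric(p$mean)
  sdc <- sqrt(p$variance$sigmasq[1])
  w <- as.numeric(p$pro)
  # two separation checks: means at least half an SD apart, and Ashman's
  # D >= 2 (below 2 a two-component fit to a unimodal sample looks like
  # this: EM splits a plain Gaussian into halves ~1.5 SD apart)
  ashman_d <- sqrt(2) * abs(diff(mns)) / sqrt(2 * sdc^2)
  if (abs(diff(mns)) < 0.5 * sdc || ashman_d < 2) {
    return(list(cutoff = stats::median(values), bimodal = FALSE,
                means = mns, sd = sdc, weights = w))
  }
  lo <- min(mns); hi <- max(mns)
  i_lo <- which.min(mns); i_hi <- which.max(mns)
  f <- function(x) w[i_lo] * stats::dnorm(x, mns[i_lo], sdc) -
                   w[i_hi] * stats::dnorm(x, mns[i_hi], sdc)
  cut <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
                  error = function(e) (lo + hi) / 2)
  list(cutoff = cut, bimodal = TRUE, means = mns, sd = sdc, weights = w)
}

#' PDL1 upregulation call from the tumor / normal-breast ratio
#'
#' A tumor is called upregulated when its expression exceeds the mean
#' normal-breast expression at least 2-fold, i.e. when the log2 difference is
#' at least 1 (boundary inclusive).
#'
#' @param tumor_log2 numeric vector of tumor log2 expression.
#' @param nb_mean_log2 scalar mean log2 expression over the pooled
#'   normal-breast samples.
#' @return character vector, `"up"` or `"no_up"`.
#' @export
call_pdl1_up <- function(tumor_log2, nb_mean_log2) {
  if (length(nb_mean_log2) != 1L || !is.finite(nb_mean_log2))
    stop("call_pdl1_up: normal-breast reference mean must be a finite scalar")
  ifelse(tumor_log2 - nb_mean_log2 >= 1, "up", "no_up")
}

#' Call all marker statuses on a pooled matrix
#'
#' ER/PR/ERBB2/Ki67 are dichotomized per dataset with [bimodal_cutoff()]
#' applied to the tumor samples (status positive iff expression >= cutoff).
#' PDL1 is called by the ratio method against the mean of all pooled
#' normal-breast samples. The clinical table is returned augmented with
#' columns `er`, `pr`, `erbb2`, `ki67` (`"positive"`/`"negative"`) and
#' `pdl1` (`"up"`/`"no_up"`).
#'
#' @param pooled a [pool_cohorts()] result (standardized space).
#' @param clinical clinical data frame with `sample_id` (tumor rows are
#'   augmented; normal-breast rows get NA statuses).
#' @param marker_genes named vector mapping marker names to gene ids
#'   (default `ESR1`, `PGR`, `ERBB2`, `MKI67`, `CD274`).
#' @return the augmented clinical table; attribute `"cutoffs"` holds the
#'   per-dataset cutoffs used and `"nb_mean"` the normal-breast reference.
#' @export
call_all_markers <- function(pooled, clinical,
                             marker_genes = MARKER_GENES) {
  stopifnot(inherits(pooled, "pooled_matrix"))
  m <- pooled$matrix
  for (g in marker_genes)
    if (!g %in% rownames(m))
      stop("call_all_markers: marker gene '", g, "' absent from the pooled matrix")
  prov <- pooled$provenance
  tumor_ids <- prov$sample_id[prov$role == "tumor"]
  nb_ids <- prov$sample_id[prov$role == "normal_breast"]
  if (length(nb_ids) == 0L)
    stop("call_all_markers: no normal-breast samples in the pool")

  status <- data.frame(sample_id = tumor_ids, stringsAsFactors = FALSE)
  cutoffs <- list()
  for (mk in c("er", "pr", "erbb2", "ki67")) {
    g <- marker_genes[[mk]]
    st <- rep(NA_character_, length(tumor_ids))
    names(st) <- tumor_ids
    for (did in unique(prov$dataset_id)) {
      ids <- prov$sample_id[prov$dataset_id == did & prov$role == "tumor"]
      bc <- bimodal_cutoff(m[g, ids])
      cutoffs[[paste(mk, did, sep = ".")]] <- bc
      st[ids] <- ifelse(m[g, ids] >= bc$cutoff, "positive", "negative")
    }
    status[[mk]] <- unname(st[tumor_ids])
  }
  nb_mean <- mean(m[marker_genes[["pdl1"]], nb_ids])
  status$pdl1 <- call_pdl1_up(m[marker_genes[["pdl1"]], tumor_ids], nb_mean)

  out <- merge(clinical, status, by = "sample_id", all.x = TRUE, sort = FALSE)
  out <- out[match(clinical$sample_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoffs") <- cutoffs
  attr(out, "nb_mean") <- nb_mean
  out
}
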