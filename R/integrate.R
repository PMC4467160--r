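# Per-dataset normalization, probe->gene collapse, luminal-A-referenced
# standardization, pooling, and a PCA batch-effect diagnostic.

#' Expression cohort container
#'
#' One dataset's log2 expression matrix (probes or genes in rows, samples in
#' columns) with its probe annotation and sample roles.
#'
#' @param dataset_id short cohort identifier.
#' @param platform free-text platform tag.
#' @param matrix numeric log2 matrix with unique row and column names.
#' @param probe_map data frame with columns `probe_id`, `gene_id`, or NULL
#'   when rows are already genes.
#' @param sample_roles named character vector over samples, values `"tumor"`
#'   or `"normal_breast"`.
#' @return object of class `expression_cohort`.
#' @export
expression_cohort <- function(dataset_id, platform, matrix, probe_map = NULL,
                              sample_roles = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("matrix must carry unique sample ids as column names")
  if (is.null(rownames(matrix)))
    stop("matrix must carry probe/gene ids as row names")
  if (is.null(sample_roles)) {
    sample_roles <- rep("tumor", ncol(matrix))
    names(sample_roles) <- colnames(matrix)
  }
  if (!all(colnames(matrix) %in% names(sample_roles)))
    stop("sample_roles must cover every sample")
  structure(list(dataset_id = dataset_id, platform = platform,
                 matrix = matrix, probe_map = probe_map,
                 sample_roles = sample_roles[colnames(matrix)]),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort '%s' (%s): %d rows x %d samples (%d tumor, %d normal breast)\n",
              x$dataset_id, x$platform, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_roles == "tumor"),
              sum(x$sample_roles == "normal_breast")))
  if (!is.null(x$probe_map))
    cat(sprintf("  probe map: %d probes -> %d genes\n",
                nrow(x$probe_map), length(unique(x$probe_map$gene_id))))
  invisible(x)
}

#' Quantile normalization
#'
#' Forces every column onto the common distribution given by the row means of
#' the column-sorted matrix; within-column ties receive the mean of the
#' reference values at their rank positions. Row and column labels are
#' preserved.
#'
#' @param m numeric matrix, no missing values.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(!is.finite(m)))
    stop("quantile_normalize: matrix contains missing or non-finite values")
  if (ncol(m) < 2L) {
    warning("quantile_normalize: single column, returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probes to genes by highest within-dataset variance
#'
#' For every gene measured by several probes, keeps the probe whose
#' within-dataset variance is largest; exact ties go to the
#' lexicographically smallest probe id. Probes absent from the map are
#' dropped.
#'
#' @param cohort an [expression_cohort()] with a probe map.
#' @return the cohort with a gene-keyed matrix (probe map consumed).
#' @export
collapse_probes <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  map <- cohort$probe_map
  if (is.null(map) || nrow(map) == 0L)
    stop("collapse_probes: empty probe map")
  map <- map[map$probe_id %in% rownames(cohort$matrix), , drop = FALSE]
  if (nrow(map) == 0L)
    stop("collapse_probes: no mapped probes present in the matrix")
  v <- apply(cohort$matrix[map$probe_id, , drop = FALSE], 1, stats::var)
  # order: gene, then decreasing variance, then probe id; keep first per gene
  ord <- order(map$gene_id, -v[map$probe_id], map$probe_id)
  map_o <- map[ord, , drop = FALSE]
  keep <- map_o[!duplicated(map_o$gene_id), , drop = FALSE]
  out <- cohort$matrix[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  cohort$matrix <- out
  cohort$probe_map <- NULL
  cohort
}

#' Standardize a cohort against a reference subpopulation
#'
#' Per gene, subtracts the mean and divides by the standard deviation of the
#' reference-subtype samples of the same dataset (the luminal-A anchor).
#' Genes whose reference SD degenerates (below 1e-6) are rescaled by the
#' dataset-wide SD instead (floored at 1e-6) and flagged. If fewer than two
#' reference samples are present
#' the whole-dataset mean/SD is used and a warning is recorded. All samples
#' (including normal breast) are transformed with the same per-gene affine
#' map, so within-dataset ranks are preserved.
#'
#' @param cohort an [expression_cohort()] keyed by gene.
#' @param subtype_labels named character vector of subtype labels covering
#'   the cohort's tumor samples.
#' @param reference_subtype the anchor subtype (default `"LumA"`).
#' @return the standardized cohort; attribute `"fallback"` is TRUE when the
#'   whole-dataset fallback was used, `"floored_genes"` lists genes whose
#'   reference SD hit the floor.
#' @export
standardize_to_reference <- function(cohort, subtype_labels,
                                     reference_subtype = "LumA") {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!reference_subtype %in% SUBTYPES)
    stop("standardize_to_reference: unknown reference subtype '",
         reference_subtype, "'")
  m <- cohort$matrix
  tumor <- names(cohort$sample_roles)[cohort$sample_roles == "tumor"]
  labs <- subtype_labels[intersect(tumor, names(subtype_labels))]
  ref <- names(labs)[!is.na(labs) & labs == reference_subtype]
  fallback <- length(ref) < 2L
  if (fallback) {
    warning("standardize_to_reference: fewer than 2 '", reference_subtype,
            "' samples in dataset ", cohort$dataset_id,
            "; falling back to whole-dataset mean/SD")
    ref <- colnames(m)
  }
  mu <- rowMeans(m[, ref, drop = FALSE])
  sd <- apply(m[, ref, drop = FALSE], 1, stats::sd)
  floored <- rownames(m)[sd < 1e-6]
  if (length(floored) > 0L) {
    # a gene constant in the reference is rescaled by the dataset-wide SD
    # (floored at 1e-6) so a degenerate anchor cannot blow up its z-scores
    sd_all <- apply(m[floored, , drop = FALSE], 1, stats::sd)
    sd[floored] <- sd_all
  }
  sd <- pmax(sd, 1e-6)
  cohort$matrix <- (m - mu) / sd
  attr(cohort, "fallback") <- fallback
  attr(cohort, "floored_genes") <- floored
  cohort
}

#' Pool standardized cohorts
#'
#' Binds cohorts column-wise over their common gene set and records each
#' sample's dataset of origin and role.
#'
#' @param cohorts list of gene-keyed [expression_cohort()] objects.
#' @return object of class `pooled_matrix`: list with `matrix`, and
#'   `provenance` (data frame `sample_id`, `dataset_id`, `role`).
#' @export
pool_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  genes <- Reduce(intersect, lapply(cohorts, function(c) rownames(c$matrix)))
  if (length(genes) == 0L)
    stop("pool_cohorts: cohorts share no genes")
  mats <- lapply(cohorts, function(c) c$matrix[genes, , drop = FALSE])
  prov <- do.call(rbind, lapply(cohorts, function(c)
    data.frame(sample_id = colnames(c$matrix),
               dataset_id = c$dataset_id,
               role = unname(c$sample_roles),
               stringsAsFactors = FALSE)))
  structure(list(matrix = do.call(cbind, mats), provenance = prov),
            class = "pooled_matrix")
}

#' @export
print.pooled_matrix <- function(x, ...) {
  cat(sprintf("Pooled matrix: %d genes x %d samples from %d dataset(s)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$provenance$dataset_id))))
  invisible(x)
}

#' PCA batch diagnostic
#'
#' Projects samples onto principal components of a gene panel and measures
#' how strongly they cluster by dataset of origin versus by biological group
#' (mean silhouette width on the leading components). Run before and after
#' standardization to verify that batch structure is removed while subtype
#' structure is retained.
#'
#' @param m genes x samples matrix.
#' @param dataset character vector of dataset labels per sample.
#' @param group optional biological labels (e.g. subtype) per sample.
#' @param gene_panel optional subset of genes to project on.
#' @param n_pc number of components used for the silhouette (default 3).
#' @return list with `var_explained` (per component), `silhouette_dataset`
#'   and `silhouette_group` (mean silhouette widths; NA when the labelling
#'   has a single level).
#' @export
pca_batch_check <- function(m, dataset, group = NULL, gene_panel = NULL,
                            n_pc = 3L) {
  if (ncol(m) < 3L) stop("pca_batch_check: need at least 3 samples")
  if (!is.null(gene_panel))
    m <- m[intersect(gene_panel, rownames(m)), , drop = FALSE]
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  sil <- function(labels) {
    labels <- as.factor(labels)
    if (nlevels(labels) < 2L) return(NA_real_)
    mean(cluster::silhouette(as.integer(labels), stats::dist(scores))[, 3])
  }
  list(var_explained = ve[seq_len(k)],
       silhouette_dataset = sil(dataset),
       silhouette_group = if (is.null(group)) NA_real_ else sil(group))
}

#' Read / write expression matrices as TSV
#'
#' Genes (or probes) in rows, samples in columns, log2 scale, first column
#' holds the row identifier.
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param m matrix to write.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
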