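# Nearest-centroid intrinsic subtyping, centroid-file-driven. The classifier
# correlates a sample's panel-gene profile with each subtype centroid
# (Spearman by default) and assigns the best-correlated subtype.

#' Assign an intrinsic molecular subtype to one sample
#'
#' Computes the correlation between the sample's expression over the centroid
#' gene panel and each subtype centroid, and returns the subtype with the
#' largest correlation. Ties are broken by the fixed subtype order LumA,
#' LumB, Basal, ERBB2, NormalLike. If no centroid correlates positively the
#' sample is labelled `"unclassified"`.
#'
#' @param sample_vector named numeric expression vector.
#' @param centroids genes x subtypes numeric matrix (all five subtypes).
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @return list with `subtype` and the named `correlations`.
#' @export
assign_subtype <- function(sample_vector, centroids, method = "spearman") {
  if (!all(SUBTYPES %in% colnames(centroids)))
    stop("assign_subtype: centroids must contain all five subtypes")
  panel <- rownames(centroids)
  present <- intersect(panel, names(sample_vector))
  if (length(present) < 0.5 * length(panel))
    stop("assign_subtype: fewer than 50% of panel genes measured")
  x <- sample_vector[present]
  cors <- vapply(SUBTYPES, function(s)
    stats::cor(x, centroids[present, s], method = method), numeric(1))
  if (all(cors <= 0))
    return(list(subtype = "unclassified", correlations = cors))
  best <- SUBTYPES[which.max(cors)]  # which.max keeps the first on exact ties
  list(subtype = best, correlations = cors)
}

#' Assign subtypes to every sample of a matrix
#'
#' @param m genes x samples matrix.
#' @param centroids genes x subtypes centroid matrix.
#' @param method correlation method passed to [assign_subtype()].
#' @return named character vector of subtype labels per sample.
#' @export
assign_subtypes <- function(m, centroids, method = "spearman") {
  out <- vapply(colnames(m), function(id)
    assign_subtype(m[, id], centroids, method = method)$subtype,
    character(1))
  names(out) <- colnames(m)
  out
}

#' Read / write a centroid table as TSV
#'
#' Rows are panel genes, columns the five subtypes.
#' @param path file path.
#' @return genes x subtypes numeric matrix.
#' @export
read_centroids_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!all(SUBTYPES %in% colnames(m)))
    stop("centroid file must contain columns: ",
         paste(SUBTYPES, collapse = ", "))
  m
}

#' @rdname read_centroids_tsv
#' @param centroids matrix to write.
#' @export
write_centroids_tsv <- function(centroids, path) {
  df <- data.frame(gene_id = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
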