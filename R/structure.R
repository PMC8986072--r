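#' PCA embedding of samples on a gene set
#'
#' Restricts the expression matrix to a gene set, standardizes each gene to
#' zero mean and unit variance across samples (zero-variance genes dropped
#' with a warning), and eigendecomposes the sample covariance on that
#' subspace.
#'
#' @param expr An `expr_mat`.
#' @param genes Gene IDs (>= 2 after dropping zero-variance genes).
#' @param meta Optional metadata joined onto the coordinates.
#' @return A list with `coordinates` (tibble: `sample_id`, `PC1`, `PC2`,
#'   ... plus metadata columns if given) and `variance_explained` (fractions
#'   summing to 1 over all returned components).
#' @export
pca_embed <- function(expr, genes, meta = NULL) {
  stopifnot(inherits(expr, "expr_mat"))
  if (!is.null(meta)) check_sample_alignment(expr, meta)
  if (ncol(expr$values) < 2) {
    abort("PCA needs >= 2 samples.", class = "triomics_input_error")
  }
  genes <- intersect(genes, gene_ids(expr))
  M <- t(expr$values[genes, , drop = FALSE])   # samples x genes
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Zero-variance gene(s) dropped from PCA: ",
      paste(colnames(M)[sds == 0], collapse = ", ")))
    M <- M[, sds > 0, drop = FALSE]
  }
  if (ncol(M) < 2) {
    abort("PCA needs >= 2 genes with nonzero variance.",
      class = "triomics_input_error")
  }
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as_tibble(pc$x, rownames = "sample_id")
  if (!is.null(meta)) coords <- left_join(coords, meta, by = "sample_id")
  list(coordinates = coords, variance_explained = ve)
}

#' Hierarchical clustering of samples on a gene set
#'
#' Agglomerative clustering of samples with distance `1 - Pearson r` over
#' the gene set (the common microarray heatmap convention) or Euclidean
#' distance, and a configurable linkage. The cophenetic distance matrix is
#' computed from the merge record. `stats::hclust` breaks merge ties
#' deterministically by lowest member index, so results are reproducible.
#'
#' @param expr An `expr_mat`.
#' @param genes Gene IDs (>= 2).
#' @param meta Optional metadata (checked for alignment, carried along).
#' @param linkage Linkage method, default `"average"`.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @return A `clustering_result`: list with `hclust` (the merge record),
#'   `cophenetic` (symmetric matrix, zero diagonal), `sample_ids`, `meta`,
#'   `linkage`, `distance`.
#' @export
hier_cluster <- function(expr, genes, meta = NULL, linkage = "average",
                         distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(inherits(expr, "expr_mat"))
  if (!is.null(meta)) check_sample_alignment(expr, meta)
  genes <- intersect(genes, gene_ids(expr))
  if (length(genes) < 2) {
    abort("Clustering needs >= 2 genes.", class = "triomics_input_error")
  }
  M <- expr$values[genes, , drop = FALSE]
  if (ncol(M) < 3) {
    abort("Clustering needs >= 3 samples.", class = "triomics_input_error")
  }
  if (distance == "correlation") {
    const <- apply(M, 2, \(v) sd(v) == 0)
    if (any(const)) {
      abort(paste0("Constant profile; correlation undefined for sample(s): ",
        paste(colnames(M)[const], collapse = ", ")),
        class = "triomics_input_error")
    }
    d <- as.dist(1 - cor(M))
  } else {
    d <- stats::dist(t(M))
  }
  hc <- hclust(d, method = linkage)
  coph <- as.matrix(cophenetic(hc))
  structure(list(hclust = hc, cophenetic = coph,
    sample_ids = colnames(M), meta = meta,
    linkage = linkage, distance = distance),
    class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d samples, %s linkage on %s distance\n",
    length(x$sample_ids), x$linkage, x$distance))
  invisible(x)
}

#' Family-adjacency fraction of a sample clustering
#'
#' Quantifies how strongly a dendrogram organizes participants by family:
#' for each non-HC sample, scores 1 if its cophenetic nearest neighbor
#' (ties broken by sample order) belongs to the same family, else 0; the
#' fraction is the mean. Under random arrangement the expected value for a
#' member of a family with `m` clustered members is `(m - 1) / (n - 1)`.
#'
#' @param cluster A `clustering_result`.
#' @param meta Sample metadata.
#' @return A list with `fraction`, `chance_level` (the analytic
#'   permutation-null expectation), `n_samples`, and `detail` (per-sample
#'   tibble: `sample_id`, `family_id`, `nearest`, `same_family`).
#' @export
family_adjacency <- function(cluster, meta) {
  stopifnot(inherits(cluster, "clustering_result"))
  ids <- cluster$sample_ids
  meta <- meta[match(ids, meta$sample_id), ]
  fam <- meta$family_id
  grp <- meta$group
  coph <- cluster$cophenetic
  n <- length(ids)
  eval_ids <- which(grp != "HC")
  if (length(eval_ids) == 0) {
    abort("No non-HC samples to evaluate.", class = "triomics_input_error")
  }
  detail <- purrr::map_dfr(eval_ids, function(i) {
    dd <- coph[i, ]
    dd[i] <- Inf
    j <- which.min(dd)  # ties: first index
    tibble(sample_id = ids[i], family_id = fam[i], nearest = ids[j],
      same_family = fam[i] == fam[j])
  })
  fam_sizes <- table(fam)
  chance <- mean((fam_sizes[fam[eval_ids]] - 1) / (n - 1))
  list(fraction = mean(detail$same_family), chance_level = unname(chance),
    n_samples = length(eval_ids), detail = detail)
}
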