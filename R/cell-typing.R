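#' Canonical major-cell-type marker map
#'
#' One canonical marker per major type: EPCAM (epithelial), THY1
#' (fibroblast), CD79A (B), CD3D (T), CD68 (myeloid), KIT (mast).
#'
#' @return named character vector, type -> marker gene.
#' @export
major_type_markers <- function() major_type_markers_default

#' Cluster cells on log-normalized expression
#'
#' PCA (up to 50 components) on the top-variance genes followed by k-means.
#' The clustering is only a vehicle for marker-based annotation; any
#' partition that separates the major types works.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param n_clusters number of clusters (default 30).
#' @param seed RNG seed for k-means.
#' @param n_top_genes number of top-variance genes used.
#' @param n_pcs maximum number of principal components.
#' @return integer cluster label per cell, named by cell id.
#' @export
cluster_cells <- function(m, n_clusters = 30, seed = 1,
                          n_top_genes = 500, n_pcs = 50) {
  require_state(m, "log2_tpm1", "cluster_cells")
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  v <- expr_values(m)
  if (nrow(v) < n_clusters)
    stop("fewer cells (", nrow(v), ") than clusters (", n_clusters, ")")
  set.seed(seed)
  if (n_clusters == nrow(v))
    return(stats::setNames(seq_len(nrow(v)), rownames(v)))
  vars <- apply(v, 2, stats::var)
  keep <- order(vars, decreasing = TRUE)[seq_len(min(n_top_genes, ncol(v)))]
  x <- v[, keep, drop = FALSE]
  x <- x[, apply(x, 2, stats::var) > 0, drop = FALSE]
  npc <- min(n_pcs, ncol(x), nrow(x) - 1)
  pcs <- stats::prcomp(x, rank. = npc, center = TRUE, scale. = FALSE)$x
  km <- stats::kmeans(pcs, centers = n_clusters, nstart = 10, iter.max = 100)
  stats::setNames(km$cluster, rownames(v))
}

#' Assign major cell types to clusters by marker expression
#'
#' Each cluster gets the type whose canonical marker has the highest mean
#' expression in that cluster. Ties are broken by lexicographic type order
#' (with a warning); clusters with all markers at zero are labelled
#' \code{"unassigned"}.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param labels cluster labels from \code{\link{cluster_cells}}.
#' @param markers named type -> marker map; all markers must be present.
#' @return list with \code{major_type} (character per cell, named) and
#'   \code{cluster_table} (per-cluster mean-marker matrix plus assignment).
#' @export
assign_major_types <- function(m, labels, markers = major_type_markers()) {
  require_state(m, "log2_tpm1", "assign_major_types")
  miss <- setdiff(markers, gene_ids(m))
  if (length(miss))
    stop("marker gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  v <- expr_values(m)[, markers, drop = FALSE]
  cl <- sort(unique(labels))
  mm <- t(vapply(cl, function(k) colMeans(v[labels == k, , drop = FALSE]),
                 numeric(length(markers))))
  rownames(mm) <- as.character(cl)
  colnames(mm) <- names(markers)
  assign_one <- function(row) {
    if (all(row == 0)) return("unassigned")
    top <- names(row)[row == max(row)]
    if (length(top) > 1) {
      warning("marker-mean tie in a cluster; lexicographic tie-break")
      top <- sort(top)[1]
    }
    top
  }
  cluster_type <- apply(mm, 1, assign_one)
  if (any(cluster_type == "unassigned"))
    warning(sum(cluster_type == "unassigned"), " cluster(s) with all markers zero")
  tab <- data.frame(cluster = rownames(mm), mm, assigned = cluster_type,
                    check.names = FALSE)
  list(major_type = stats::setNames(cluster_type[as.character(labels)],
                                    names(labels)),
       cluster_table = tab)
}

#' Per-patient, per-tissue major-type proportions
#'
#' @param annotation a \code{cell_annotation} with \code{major_type} set.
#' @return data.frame(patient_id, tissue, major_type, n, fraction); fractions
#'   sum to 1 within each (patient, tissue).
#' @export
type_proportions <- function(annotation) {
  stopifnot(inherits(annotation, "cell_annotation"))
  if (all(is.na(annotation$major_type)))
    stop("major types not assigned")
  counts <- stats::aggregate(cbind(n = rep(1, nrow(annotation))),
                             by = list(patient_id = annotation$patient_id,
                                       tissue = annotation$tissue,
                                       major_type = annotation$major_type),
                             FUN = sum)
  tot <- stats::ave(counts$n, counts$patient_id, counts$tissue, FUN = sum)
  counts$fraction <- counts$n / tot
  counts[order(counts$patient_id, counts$tissue, counts$major_type), ]
}
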