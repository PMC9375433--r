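#' Parameters for expression-derived CNV inference
#'
#' @param smoothing_genes genes averaged around each gene along the
#'   chromosome (default 100: 50 preceding, the gene, 49 following).
#' @param window_bp genomic window size for relative CNV scores (default
#'   10 Mb).
#' @param min_cluster_cells CNV clusters are kept only when strictly larger
#'   than this (default 10).
#' @param n_cnv_clusters number of CNV clusters (default 4).
#' @param clip centered gene scores are clipped to +/- this value
#'   (default 3).
#' @export
cnv_params <- function(smoothing_genes = 100, window_bp = 1e7,
                       min_cluster_cells = 10, n_cnv_clusters = 4,
                       clip = 3) {
  stopifnot(smoothing_genes >= 1, window_bp > 0, clip > 0)
  structure(list(smoothing_genes = smoothing_genes, window_bp = window_bp,
                 min_cluster_cells = min_cluster_cells,
                 n_cnv_clusters = n_cnv_clusters, clip = clip),
            class = "cnv_params")
}

# order genes by chromosome then start; drop genes without coordinates and
# chromosomes with < 2 genes
ordered_genes <- function(m, annotation) {
  ann <- annotation[match(gene_ids(m), annotation$gene_id), , drop = FALSE]
  n_missing <- sum(is.na(ann$chromosome))
  if (n_missing)
    message(n_missing, " gene(s) without coordinates excluded from CNV inference")
  ann <- ann[!is.na(ann$chromosome), , drop = FALSE]
  tab <- table(ann$chromosome)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("chromosome(s) with < 2 annotated genes excluded: ",
            paste(small, collapse = ", "))
    ann <- ann[!(ann$chromosome %in% small), , drop = FALSE]
  }
  ann[order(ann$chromosome, ann$start), , drop = FALSE]
}

#' Moving average of expression along genomic gene order
#'
#' Per chromosome, each gene's CNV score is the mean expression of a window
#' of \code{k} consecutive genes centered on it (floor(k/2) preceding, the
#' gene, the rest following), truncated at chromosome ends.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param annotation \code{gene_annotation} for the matrix genes.
#' @param k window size in genes (default 100).
#' @return list with \code{smoothed} (cells x genes matrix, genes in
#'   genomic order) and \code{annotation} (the retained, ordered genes).
#' @export
gene_moving_average <- function(m, annotation, k = 100) {
  require_state(m, "log2_tpm1", "gene_moving_average")
  moving_average_matrix(expr_values(m), m, annotation, k)
}

# core smoother on a plain cells x genes matrix (values may already be
# centered relative expression)
moving_average_matrix <- function(values, m, annotation, k) {
  ann <- ordered_genes(m, annotation)
  if (!nrow(ann)) stop("no genes with usable coordinates")
  v <- values[, ann$gene_id, drop = FALSE]
  half_lo <- floor(k / 2)
  half_hi <- k - half_lo - 1
  sm <- v
  for (ch in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == ch)
    x <- v[, idx, drop = FALSE]
    nc <- length(idx)
    # running means via cumulative sums over the gene axis
    cs <- cbind(0, t(apply(x, 1, cumsum)))
    lo <- pmax(seq_len(nc) - half_lo, 1L)
    hi <- pmin(seq_len(nc) + half_hi, nc)
    sm[, idx] <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
      rep(hi - lo + 1L, each = nrow(x))
  }
  list(smoothed = sm, annotation = ann)
}

#' Infer a relative CNV profile from expression
#'
#' The package's composed CNV pipeline: per-gene relative expression against
#' the normal-cell mean, clipped to \code{+/- clip} (bounding the leverage
#' of strongly differential genes such as lineage markers before any
#' positional averaging), then smoothed along genomic gene order, re-centered
#' on the normal cells so their per-gene mean is exactly zero, and averaged
#' into genomic windows.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state (epithelial cells,
#'   tumor and normal).
#' @param annotation \code{gene_annotation} for the matrix genes.
#' @param normal_cell_ids reference (normal epithelial) cell ids.
#' @param params a \code{\link{cnv_params}}.
#' @return a \code{cnv_profile} (see \code{\link{window_scores}}).
#' @export
infer_cnv_profile <- function(m, annotation, normal_cell_ids,
                              params = cnv_params()) {
  require_state(m, "log2_tpm1", "infer_cnv_profile")
  rel <- center_by_normals(expr_values(m), normal_cell_ids,
                           clip = params$clip)
  sm <- moving_average_matrix(rel, m, annotation, params$smoothing_genes)
  # exact zero mean over normals per gene after smoothing
  cen <- center_by_normals(sm$smoothed, normal_cell_ids, clip = Inf)
  window_scores(cen, sm$annotation, params$window_bp)
}

#' Center smoothed CNV scores on normal epithelial cells
#'
#' Subtracts, per gene, the mean smoothed score over the normal reference
#' cells, then clips to \code{+/- clip}.
#'
#' @param smoothed cells x genes smoothed matrix (from
#'   \code{\link{gene_moving_average}}).
#' @param normal_cell_ids reference cell ids (>= 1 required).
#' @param clip clipping bound (default 3).
#' @return centered matrix of the same shape.
#' @export
center_by_normals <- function(smoothed, normal_cell_ids, clip = 3) {
  normal_cell_ids <- intersect(normal_cell_ids, rownames(smoothed))
  if (!length(normal_cell_ids))
    stop("no normal reference cells present in the matrix")
  ref <- colMeans(smoothed[normal_cell_ids, , drop = FALSE])
  centered <- sweep(smoothed, 2, ref)
  pmin(pmax(centered, -clip), clip)
}

#' Relative CNV scores per genomic window
#'
#' Averages centered gene scores within half-open windows of
#' \code{window_bp} laid along each chromosome from 0; a gene belongs to the
#' window containing its start. Empty windows are dropped.
#'
#' @param centered matrix from \code{\link{center_by_normals}}.
#' @param annotation the ordered \code{gene_annotation} matching its genes.
#' @param window_bp window size (default 10 Mb).
#' @return object of class \code{cnv_profile}: list with \code{scores}
#'   (cells x windows) and \code{windows} (chromosome, start, end, n_genes).
#' @export
window_scores <- function(centered, annotation, window_bp = 1e7) {
  ann <- annotation[match(colnames(centered), annotation$gene_id), ]
  wi <- floor(ann$start / window_bp)
  key <- paste(ann$chromosome, wi, sep = ":")
  uk <- unique(key[order(ann$chromosome, wi)])
  scores <- vapply(uk, function(kk)
    rowMeans(centered[, key == kk, drop = FALSE]), numeric(nrow(centered)))
  if (nrow(centered) == 1) scores <- matrix(scores, nrow = 1,
                                            dimnames = list(rownames(centered), uk))
  parts <- do.call(rbind, strsplit(uk, ":"))
  win <- data.frame(chromosome = parts[, 1],
                    start = as.numeric(parts[, 2]) * window_bp,
                    end = (as.numeric(parts[, 2]) + 1) * window_bp,
                    n_genes = as.vector(table(key)[uk]),
                    stringsAsFactors = FALSE)
  structure(list(scores = scores, windows = win), class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("cnv_profile: %d cells x %d windows over %d chromosome(s)\n",
              nrow(x$scores), nrow(x$windows),
              length(unique(x$windows$chromosome))))
  invisible(x)
}

#' Cluster cells by CNV profile
#'
#' Ward-linkage hierarchical clustering of the window-score vectors;
#' clusters must have strictly more than \code{min_cluster_cells} cells to
#' be retained, others are labelled \code{"dropped"}.
#'
#' @param profile a \code{cnv_profile}.
#' @param n_cnv_clusters number of clusters (default 4).
#' @param min_cluster_cells strict retention threshold (default 10).
#' @return character label per cell (cluster number or \code{"dropped"}),
#'   named by cell id.
#' @export
cluster_cnv <- function(profile, n_cnv_clusters = 4, min_cluster_cells = 10) {
  stopifnot(inherits(profile, "cnv_profile"))
  x <- profile$scores
  k <- min(n_cnv_clusters, nrow(unique(x)))
  grp <- if (k == 1) rep(1L, nrow(x)) else
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = k)
  sizes <- table(grp)
  lab <- as.character(grp)
  lab[sizes[lab] <= min_cluster_cells] <- "dropped"
  if (all(lab == "dropped")) warning("all CNV clusters dropped")
  stats::setNames(lab, rownames(x))
}

#' Normalized bulk WGS depth per genomic window
#'
#' Assigns each read to the half-open \code{window_bp} window containing its
#' position and divides window counts by the sample's total reads.
#'
#' @param read_table data.frame(chromosome, position, sample).
#' @param window_bp window size (default 10 Mb).
#' @return data.frame(sample, chromosome, start, end, n_reads, depth) with
#'   per-sample depths summing to 1.
#' @export
wgs_window_profile <- function(read_table, window_bp = 1e7) {
  need <- c("chromosome", "position", "sample")
  miss <- setdiff(need, names(read_table))
  if (length(miss)) stop("read table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(read_table)) stop("empty read table")
  wi <- floor(read_table$position / window_bp)
  agg <- stats::aggregate(cbind(n_reads = rep(1L, nrow(read_table))),
                          by = list(sample = read_table$sample,
                                    chromosome = read_table$chromosome,
                                    start = wi * window_bp),
                          FUN = sum)
  tot <- stats::ave(agg$n_reads, agg$sample, FUN = sum)
  agg$end <- agg$start + window_bp
  agg$depth <- agg$n_reads / tot
  agg[order(agg$sample, agg$chromosome, agg$start),
      c("sample", "chromosome", "start", "end", "n_reads", "depth")]
}

#' Sign concordance between scRNA CNV profile and bulk WGS depth
#'
#' For every shared window, compares the sign of the mean tumor-cell scRNA
#' CNV score against the sign of the log tumor/normal WGS depth ratio,
#' restricted to non-neutral windows (|log2 depth ratio| at or above
#' \code{neutral_log2}).
#'
#' @param profile a \code{cnv_profile} (tumor cells only, or pass
#'   \code{tumor_cells}).
#' @param wgs_profile output of \code{\link{wgs_window_profile}} with
#'   samples \code{"tumor"} and \code{"normal"}.
#' @param tumor_cells optional subset of profile cells to average.
#' @param neutral_log2 neutrality band on the WGS log2 ratio (default 0.2).
#' @return list(per_window, agreement, n_nonneutral); \code{agreement} is NA
#'   when no non-neutral window exists.
#' @export
concordance <- function(profile, wgs_profile, tumor_cells = NULL,
                        neutral_log2 = 0.2) {
  stopifnot(inherits(profile, "cnv_profile"))
  sc <- profile$scores
  if (!is.null(tumor_cells)) sc <- sc[intersect(tumor_cells, rownames(sc)), ,
                                      drop = FALSE]
  sc_mean <- colMeans(sc)
  tum <- wgs_profile[wgs_profile$sample == "tumor", ]
  nor <- wgs_profile[wgs_profile$sample == "normal", ]
  key_sc <- paste(profile$windows$chromosome, profile$windows$start)
  key_t <- paste(tum$chromosome, tum$start)
  key_n <- paste(nor$chromosome, nor$start)
  shared <- intersect(key_sc, intersect(key_t, key_n))
  if (!length(shared)) stop("no shared windows between scRNA and WGS profiles")
  ratio <- log2(tum$depth[match(shared, key_t)] /
                  nor$depth[match(shared, key_n)])
  scm <- sc_mean[match(shared, key_sc)]
  nonneutral <- abs(ratio) >= neutral_log2
  per_window <- data.frame(window = shared, scrna_mean = scm,
                           wgs_log2_ratio = ratio, nonneutral = nonneutral,
                           agree = sign(scm) == sign(ratio),
                           stringsAsFactors = FALSE)
  agreement <- if (any(nonneutral)) mean(per_window$agree[nonneutral]) else NA_real_
  if (!any(nonneutral))
    message("no non-neutral windows; agreement undefined")
  list(per_window = per_window, agreement = agreement,
       n_nonneutral = sum(nonneutral))
}
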