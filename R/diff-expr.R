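#' Parameters for rank-based marker detection
#'
#' Mirrors the conventional one-vs-rest Wilcoxon marker screen: genes are
#' pre-filtered by detection fraction and log fold change before testing,
#' and only positive markers are kept by default.
#'
#' @param logfc_threshold minimum |log fold change| (default 1.5).
#' @param min_pct minimum detection fraction in at least one of the two
#'   groups (default 0.25).
#' @param only_pos keep only genes up in the group (default TRUE).
#' @param alpha Benjamini-Hochberg adjusted-p cutoff on returned rows.
#' @param fc_base \code{"log2"} (difference of log2(TPM+1) means) or
#'   \code{"natural"} (same difference expressed in natural-log units, for
#'   comparability with tools whose fold changes are natural-log based).
#' @export
de_params <- function(logfc_threshold = 1.5, min_pct = 0.25, only_pos = TRUE,
                      alpha = 0.05, fc_base = c("log2", "natural")) {
  fc_base <- match.arg(fc_base)
  stopifnot(logfc_threshold >= 0, min_pct >= 0, min_pct <= 1, alpha > 0)
  structure(list(logfc_threshold = logfc_threshold, min_pct = min_pct,
                 only_pos = only_pos, alpha = alpha, fc_base = fc_base),
            class = "de_params")
}

# two-sided rank-sum p-value: exact enumeration when both groups are small
# and tie-free, otherwise normal approximation with tie correction
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 12 && length(y) <= 12 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' One-vs-rest differential expression by Wilcoxon rank-sum
#'
#' For every group, each gene passing the detection and fold-change filters
#' is tested against all remaining cells with a two-sided Wilcoxon rank-sum
#' test; p-values are Benjamini-Hochberg adjusted over the genes actually
#' tested within the group, and rows with adjusted p below \code{alpha} are
#' returned sorted by adjusted p then decreasing log fold change.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param groups group label per cell (length = number of cells).
#' @param params a \code{\link{de_params}}.
#' @return data.frame(gene_id, group, log_fc, pct_in, pct_out, p_value,
#'   adjusted_p) of class \code{de_result}.
#' @export
find_markers <- function(m, groups, params = de_params()) {
  require_state(m, "log2_tpm1", "find_markers")
  v <- expr_values(m)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(v))
  gs <- sort(unique(groups))
  if (length(gs) < 2) stop("find_markers needs >= 2 groups")
  small <- gs[table(factor(groups, gs)) < 3]
  if (length(small))
    stop("group(s) with < 3 cells: ", paste(small, collapse = ", "))

  out <- lapply(gs, function(g) {
    inc <- groups == g
    vi <- v[inc, , drop = FALSE]; vo <- v[!inc, , drop = FALSE]
    pct_in <- colMeans(vi > 0); pct_out <- colMeans(vo > 0)
    lfc <- colMeans(vi) - colMeans(vo)
    if (params$fc_base == "natural") lfc <- lfc * log(2)
    keep <- pmax(pct_in, pct_out) >= params$min_pct &
      abs(lfc) >= params$logfc_threshold
    if (params$only_pos) keep <- keep & lfc > 0
    idx <- which(keep)
    if (!length(idx)) return(NULL)
    p <- vapply(idx, function(j) rank_sum_p(vi[, j], vo[, j]), numeric(1))
    data.frame(gene_id = colnames(v)[idx], group = g, log_fc = lfc[idx],
               pct_in = pct_in[idx], pct_out = pct_out[idx],
               p_value = p, adjusted_p = stats::p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), group = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      adjusted_p = numeric())
  res <- res[res$adjusted_p < params$alpha, , drop = FALSE]
  res <- res[order(res$group, res$adjusted_p, -res$log_fc), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Tumor-versus-normal differential genes among epithelial cells
#'
#' Both directions are tested at the given |log2 fold change| cutoff and the
#' significant genes are partitioned by sign.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param annotation \code{cell_annotation}; only epithelial cells are used.
#' @param log2fc_cutoff minimum |log2 fold change| (default 2).
#' @param alpha adjusted-p cutoff.
#' @return list(up = character, down = character, table = de_result rows for
#'   the tumor group).
#' @export
tumor_vs_normal_degs <- function(m, annotation, log2fc_cutoff = 2,
                                 alpha = 0.05) {
  stopifnot(inherits(annotation, "cell_annotation"))
  is_epi <- is.na(annotation$major_type) | annotation$major_type == "epithelial"
  epi <- annotation$cell_id[is_epi & annotation$tissue %in% c("tumor", "normal")]
  ann <- annotation[match(epi, annotation$cell_id), ]
  if (length(unique(ann$tissue)) < 2)
    stop("need both tumor and normal epithelial cells")
  sub <- m[match(epi, cell_ids(m)), seq_len(ncol(m$values))]
  res <- find_markers(sub, ann$tissue,
                      de_params(logfc_threshold = log2fc_cutoff,
                                only_pos = FALSE, alpha = alpha))
  tum <- res[res$group == "tumor", , drop = FALSE]
  list(up = tum$gene_id[tum$log_fc > 0], down = tum$gene_id[tum$log_fc < 0],
       table = tum)
}
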