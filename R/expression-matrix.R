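#' Expression matrix with an explicit normalization state
#'
#' A light container for a cell x gene quantification matrix. Rows are cells,
#' columns are genes, and the object records whether values are raw counts,
#' transcripts-per-million (TPM), or log2(TPM+1). State transitions are
#' one-way: counts -> tpm -> log2_tpm1.
#'
#' @param values numeric matrix (base or \code{Matrix} sparse), cells in rows,
#'   genes in columns, with unique row and column names.
#' @param state one of \code{"counts"}, \code{"tpm"}, \code{"log2_tpm1"}.
#' @return an object of class \code{expr_matrix}.
#' @export
expression_matrix <- function(values, state = c("counts", "tpm", "log2_tpm1")) {
  state <- match.arg(state)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires cell (row) and gene (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (min_value(values) < 0) stop("expression values must be nonnegative")
  # sparse storage pays off below ~30% density; numeric results are identical
  if (!inherits(values, "sparseMatrix") && is.matrix(values)) {
    dens <- mean(values != 0)
    if (!is.na(dens) && dens < 0.3 && prod(dim(values)) > 1e4)
      values <- Matrix::Matrix(values, sparse = TRUE)
  }
  structure(list(values = values, state = state), class = "expr_matrix")
}

min_value <- function(x) if (inherits(x, "sparseMatrix")) min(0, x@x, Inf) else suppressWarnings(min(x, Inf))

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Cell and gene identifiers
#' @param m an \code{expr_matrix}.
#' @return character vector of ids.
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Dense numeric values of an expression matrix
#' @param m an \code{expr_matrix}.
#' @return base numeric matrix, cells in rows.
#' @export
expr_values <- function(m) as.matrix(m$values)

#' Subset an expression matrix
#' @param x an \code{expr_matrix}.
#' @param i,j cell and gene indices (any form base subsetting accepts).
#' @param ... unused.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, x$state)
}

require_state <- function(m, state, what) {
  if (!inherits(m, "expr_matrix")) stop(what, " requires an expr_matrix")
  if (m$state != state)
    stop(what, " requires a matrix in '", state, "' state, got '", m$state, "'")
  invisible(m)
}

#' TPM normalization
#'
#' Rescales each cell so its values sum to one million.
#'
#' @param m an \code{expr_matrix} in \code{counts} state.
#' @return an \code{expr_matrix} in \code{tpm} state.
#' @export
tpm_normalize <- function(m) {
  require_state(m, "counts", "tpm_normalize")
  tot <- Matrix::rowSums(m$values)
  if (any(tot == 0))
    stop("cannot TPM-normalize all-zero cell(s): ",
         paste(utils::head(rownames(m$values)[tot == 0], 5), collapse = ", "))
  v <- m$values / tot * 1e6
  expression_matrix(v, "tpm")
}

#' Log transform of a TPM matrix
#'
#' Elementwise log2(x + 1).
#'
#' @param m an \code{expr_matrix} in \code{tpm} state.
#' @return an \code{expr_matrix} in \code{log2_tpm1} state.
#' @export
log_transform <- function(m) {
  require_state(m, "tpm", "log_transform")
  # log2(x+1) of a sparse matrix is dense only in its nonzeros
  v <- m$values
  if (inherits(v, "sparseMatrix")) {
    v@x <- log2(v@x + 1)
  } else {
    v <- log2(v + 1)
  }
  expression_matrix(v, "log2_tpm1")
}

#' Cell-level quality-control parameters
#'
#' Defaults reflect plate-based (STRT-seq-like) depth: at least 1000 detected
#' genes, at least 10,000 total counts, and at most 30\% mitochondrial counts.
#' Mitochondrial genes are recognized by the "MT-" gene-id prefix.
#'
#' @param min_genes_detected minimum number of genes with count > 0.
#' @param min_total_count minimum total counts per cell.
#' @param max_mito_fraction maximum fraction of counts on mitochondrial genes.
#' @export
qc_params <- function(min_genes_detected = 1000, min_total_count = 10000,
                      max_mito_fraction = 0.3) {
  stopifnot(min_genes_detected >= 0, min_total_count >= 0,
            max_mito_fraction >= 0)
  structure(list(min_genes_detected = min_genes_detected,
                 min_total_count = min_total_count,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_params")
}

#' Filter low-quality cells
#'
#' Removes cells failing any of the thresholds in \code{params} and reports
#' per-criterion removal counts plus the overall retention percentage.
#'
#' @param m an \code{expr_matrix} in \code{counts} state.
#' @param params a \code{\link{qc_params}} object.
#' @return list with \code{matrix} (retained cells) and \code{report}.
#' @export
qc_filter <- function(m, params = qc_params()) {
  require_state(m, "counts", "qc_filter")
  v <- m$values
  genes_det <- Matrix::rowSums(v > 0)
  tot <- Matrix::rowSums(v)
  mito <- grepl("^MT-", colnames(v))
  mito_frac <- if (any(mito)) Matrix::rowSums(v[, mito, drop = FALSE]) / pmax(tot, 1) else rep(0, nrow(v))

  fail_genes <- genes_det < params$min_genes_detected
  fail_total <- tot < params$min_total_count
  fail_mito  <- mito_frac > params$max_mito_fraction
  keep <- !(fail_genes | fail_total | fail_mito)

  report <- list(
    n_input = nrow(v),
    n_retained = sum(keep),
    removed_low_genes = sum(fail_genes),
    removed_low_total = sum(fail_total),
    removed_high_mito = sum(fail_mito),
    retention_pct = round(100 * sum(keep) / nrow(v), 1)
  )
  class(report) <- "qc_report"
  if (sum(keep) == 0) warning("QC thresholds removed all cells")
  list(matrix = m[keep, seq_len(ncol(v))], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: retained %d / %d cells (%.1f%%)\n",
              x$n_retained, x$n_input, x$retention_pct))
  cat(sprintf("  removed: %d low gene count, %d low total count, %d high mito fraction\n",
              x$removed_low_genes, x$removed_low_total, x$removed_high_mito))
  invisible(x)
}
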