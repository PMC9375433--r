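#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. \code{format = "mtx"}: a MatrixMarket
#' sparse matrix with genes in rows and cells in columns, plus two sidecar
#' index files (one id per line) for genes and cells; by default these are
#' found by replacing the \code{.mtx} suffix with \code{_genes.tsv} and
#' \code{_cells.tsv}. \code{format = "tsv"}: a dense tab-separated table with
#' a header row of gene ids and the first column holding cell ids.
#'
#' @param path path to the \code{.mtx} or \code{.tsv} file.
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @param state normalization state of the stored values.
#' @param genes_path,cells_path optional explicit index file paths (mtx only).
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, format = c("mtx", "tsv"),
                            state = c("counts", "tpm", "log2_tpm1"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  state <- match.arg(state)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- sub("\\.mtx$", "_genes.tsv", path)
    if (is.null(cells_path)) cells_path <- sub("\\.mtx$", "_cells.tsv", path)
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("index file not found: ", p)
    mm <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(mm) != length(genes))
      stop(sprintf("%s: %d matrix rows but %d gene ids in %s",
                   path, nrow(mm), length(genes), genes_path))
    if (ncol(mm) != length(cells))
      stop(sprintf("%s: %d matrix columns but %d cell ids in %s",
                   path, ncol(mm), length(cells), cells_path))
    if (anyDuplicated(genes)) stop(genes_path, ": duplicate gene ids")
    if (anyDuplicated(cells)) stop(cells_path, ": duplicate cell ids")
    v <- Matrix::t(mm)
    dimnames(v) <- list(cells, genes)
    expression_matrix(Matrix::Matrix(v, sparse = TRUE), state)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    v <- as.matrix(df)
    if (!is.numeric(v)) stop(path, ": non-numeric values in expression table")
    expression_matrix(v, state)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of \code{\link{read_expression}}; the MTX layout stores genes in
#' rows and writes the two sidecar index files next to the matrix.
#'
#' @param m an \code{expr_matrix}.
#' @param path output path (\code{.mtx} or \code{.tsv}).
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @export
write_expression <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "expr_matrix"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::t(Matrix::Matrix(m$values, sparse = TRUE)), path)
    writeLines(gene_ids(m), sub("\\.mtx$", "_genes.tsv", path))
    writeLines(cell_ids(m), sub("\\.mtx$", "_cells.tsv", path))
  } else {
    df <- as.data.frame(expr_values(m), check.names = FALSE)
    utils::write.table(cbind(cell_id = rownames(df), df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or construct a cell annotation table
#'
#' @param x a data.frame or a path to a CSV with columns \code{cell_id},
#'   \code{patient_id}, \code{tissue} and optionally \code{major_type},
#'   \code{cancer_subtype}.
#' @return a validated data.frame of class \code{cell_annotation}.
#' @export
cell_annotation <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  need <- c("cell_id", "patient_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cell annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in annotation")
  ok_tissue <- c("normal", "tumor", "lymph_node_metastasis")
  bad <- setdiff(unique(df$tissue), ok_tissue)
  if (length(bad)) stop("unknown tissue class(es): ", paste(bad, collapse = ", "))
  if (is.null(df$major_type)) df$major_type <- NA_character_
  if (is.null(df$cancer_subtype)) df$cancer_subtype <- NA_character_
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Read or construct a gene annotation table
#'
#' Coordinates are stored 0-based half-open internally. BED input is taken
#' as-is; GTF (1-based closed) is converted on ingest. Parsing of both
#' formats is delegated to \pkg{rtracklayer}.
#'
#' @param x a data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end} (0-based half-open) and optionally
#'   \code{strand}, or a path to a BED/GTF file.
#' @param format \code{"bed"} or \code{"gtf"}; guessed from the file suffix
#'   when \code{NULL}.
#' @return a data.frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(x, format = NULL) {
  if (is.character(x)) {
    if (is.null(format))
      format <- if (grepl("\\.bed$", x, ignore.case = TRUE)) "bed" else "gtf"
    gr <- rtracklayer::import(x, format = format)
    if (format == "gtf") {
      md <- S4Vectors::mcols(gr)
      if (!is.null(md$type) && any(md$type == "gene")) gr <- gr[md$type == "gene"]
      ids <- S4Vectors::mcols(gr)$gene_id
      if (is.null(ids)) ids <- S4Vectors::mcols(gr)$gene_name
    } else {
      ids <- S4Vectors::mcols(gr)$name
    }
    if (is.null(ids)) stop(x, ": no gene identifiers found")
    df <- data.frame(gene_id = as.character(ids),
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     # GRanges is 1-based closed; internal storage half-open
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
    if (is.null(df$strand)) df$strand <- "*"
  }
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene annotation")
  if (any(df$start >= df$end)) stop("gene annotation requires start < end (0-based half-open)")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write a gene annotation table as BED
#'
#' @param ann a \code{gene_annotation} data.frame.
#' @param path output BED path.
#' @export
write_gene_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    ann$chromosome,
    IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"),
    name = ann$gene_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a mitochondrial allele-frequency matrix
#'
#' @param path TSV with cells in rows (first column \code{cell_id}) and
#'   variant ids (\code{"<position>_<alt>"}) as remaining column names;
#'   empty fields are treated as missing (insufficient coverage).
#' @return numeric matrix, cells x variants, values in [0,1] or NA.
#' @export
read_mito_afm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop(path, ": allele frequencies outside [0,1]")
  m
}
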