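#' End-to-end lineage classification of tumor epithelial cells
#'
#' Runs the full lineage workflow on a log-normalized matrix of epithelial
#' cells: attribution scoring, subtype assignment, archetype selection,
#' signature discovery, and ternary scoring of the tumor cells.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state (epithelial cells).
#' @param annotation \code{cell_annotation} covering the cells of \code{m}.
#' @param panel a \code{\link{lineage_marker_panel}}.
#' @param params an \code{\link{attribution_params}}.
#' @param de a \code{\link{de_params}} for signature discovery.
#' @param which_panel panel used for attribution (\code{"full"} or
#'   \code{"trio"}).
#' @return object of class \code{lineage_classification}: annotation with
#'   subtypes filled in, attribution scores, archetypes, signatures, ternary
#'   scores and the per-patient mixed fractions.
#' @export
classify_lineages <- function(m, annotation, panel = lineage_marker_panel(),
                              params = attribution_params(),
                              de = de_params(),
                              which_panel = "full") {
  require_state(m, "log2_tpm1", "classify_lineages")
  stopifnot(inherits(annotation, "cell_annotation"))
  ann <- annotation[match(cell_ids(m), annotation$cell_id), ]
  tumor <- ann$tissue %in% c("tumor", "lymph_node_metastasis")

  scores <- attribution_scores(m, panel, params, which_panel = which_panel)
  tum_scores <- scores[tumor, , drop = FALSE]
  class(tum_scores) <- class(scores)
  asg <- assign_subtypes(tum_scores, params)
  ann$cancer_subtype[tumor] <- unname(asg$subtype[ann$cell_id[tumor]])
  ann <- cell_annotation(ann)

  m_tumor <- m[which(tumor), seq_len(ncol(m$values))]
  arch <- select_archetype_cells(m_tumor, panel, params$top_n_cells)
  sig <- tryCatch(
    lineage_signatures(m, arch, de, params$top_n_degs),
    error = function(e) {
      warning("signature discovery failed: ", conditionMessage(e))
      NULL
    })
  tern <- if (!is.null(sig) && all(lengths(sig) > 0))
    ternary_scores(m_tumor, sig) else NULL

  structure(list(annotation = ann, scores = scores, subtype_groups = asg,
                 archetypes = arch, signatures = sig, ternary = tern,
                 mixed_fraction = mixed_lineage_fraction(ann),
                 which_panel = which_panel),
            class = "lineage_classification")
}

#' @export
print.lineage_classification <- function(x, ...) {
  tum <- x$annotation[!is.na(x$annotation$cancer_subtype), ]
  cat("lineage_classification\n")
  cat(sprintf("  %d tumor epithelial cells subtyped (%s panel)\n",
              nrow(tum), x$which_panel))
  tab <- sort(table(tum$cancer_subtype), decreasing = TRUE)
  for (nm in names(tab)) cat(sprintf("    %-16s %d\n", nm, tab[[nm]]))
  mixed <- sum(tum$cancer_subtype %in% mixed_subtype_labels())
  cat(sprintf("  mixed-lineage cells: %d / %d (%.1f%%)\n",
              mixed, nrow(tum), 100 * mixed / max(nrow(tum), 1)))
  invisible(x)
}

#' @export
summary.lineage_classification <- function(object, ...) {
  cat("Per-patient mixed-lineage fractions:\n")
  print(object$mixed_fraction)
  cat("\nSubtype group means (A/S/N attribution):\n")
  print(object$subtype_groups$group_means)
  invisible(object$mixed_fraction)
}

#' Ternary scatter of lineage compositions
#'
#' Projects each tumor cell's (a, s, n) composition onto the 2-simplex and
#' plots it, colored by subtype. Cells with undefined composition are
#' omitted.
#'
#' @param x a \code{lineage_classification}.
#' @param ... passed to \code{plot}.
#' @export
plot.lineage_classification <- function(x, ...) {
  if (is.null(x$ternary)) stop("no ternary scores in this object")
  tern <- x$ternary[!is.na(x$ternary$comp_a), ]
  # simplex corners: A = (0,0), S = (1,0), N = (0.5, sqrt(3)/2)
  px <- tern$comp_s + 0.5 * tern$comp_n
  py <- sqrt(3) / 2 * tern$comp_n
  sub <- x$annotation$cancer_subtype[match(tern$cell_id,
                                           x$annotation$cell_id)]
  cols <- grDevices::rainbow(length(unique(sub)))
  names(cols) <- unique(sub)
  graphics::plot(px, py, col = cols[sub], pch = 16, asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = "Lineage composition (A bottom-left, S bottom-right, N top)",
                 ...)
  graphics::segments(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2),
                     c(1, 0.5, 0), c(0, sqrt(3) / 2, 0))
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(x)
}
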