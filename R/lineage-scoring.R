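#' Lineage marker panels for ADC, SCC and NET programs
#'
#' The full panels are the cancer-type-associated gene sets used for
#' attribution scoring (7 neuroendocrine, 4 squamous, 6 adenocarcinoma
#' genes); the classical trios are the three-marker subsets used to rank
#' archetype cells (NKX2-1/KRT7/NAPSA for ADC, TP63/KRT5/KRT6A for SCC,
#' CHGB/SYP/NCAM1 for NET).
#'
#' @return list of class \code{lineage_panel} with \code{full} and
#'   \code{trio}, each a list with elements ADC, SCC, NET.
#' @export
lineage_marker_panel <- function() {
  panel <- list(
    full = list(
      ADC = c("NKX2-1", "KRT7", "NAPSA", "MUC1", "KRT8", "KRT18"),
      SCC = c("KRT5", "KRT6A", "TP63", "SOX2"),
      NET = c("CHGA", "CHGB", "ASCL1", "SYP", "NEUROD1", "NCAM1", "SST")),
    trio = list(
      ADC = c("NKX2-1", "KRT7", "NAPSA"),
      SCC = c("TP63", "KRT5", "KRT6A"),
      NET = c("CHGB", "SYP", "NCAM1")))
  class(panel) <- "lineage_panel"
  panel
}

#' Parameters for attribution scoring and subtype assignment
#'
#' @param marker_floor log2(TPM+1) floor: marker values below it are zeroed
#'   before taking the per-lineage maximum (default 5).
#' @param n_groups number of subtype groups for hierarchical clustering
#'   (default 5).
#' @param top_n_cells archetype cells per lineage (default 50).
#' @param top_n_degs signature genes per lineage (default 50).
#' @export
attribution_params <- function(marker_floor = 5, n_groups = 5,
                               top_n_cells = 50, top_n_degs = 50) {
  stopifnot(marker_floor >= 0, n_groups >= 1, top_n_cells >= 1,
            top_n_degs >= 1)
  structure(list(marker_floor = marker_floor, n_groups = n_groups,
                 top_n_cells = top_n_cells, top_n_degs = top_n_degs),
            class = "attribution_params")
}

panel_in_matrix <- function(m, genes, what) {
  present <- intersect(genes, gene_ids(m))
  miss <- setdiff(genes, present)
  if (length(miss))
    warning(what, ": panel gene(s) absent, skipped: ",
            paste(miss, collapse = ", "))
  present
}

#' Cancer-type attribution scores
#'
#' Per cell and lineage: zero every panel gene below the marker floor, then
#' take the maximum over the lineage's panel. Cells with all three scores
#' zero are flagged unclassified.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state (epithelial cells).
#' @param panel a \code{\link{lineage_marker_panel}}; \code{which_panel}
#'   chooses the full panels or the classical trios.
#' @param params an \code{\link{attribution_params}}.
#' @param which_panel \code{"full"} or \code{"trio"}.
#' @return data.frame(cell_id, A, S, N, unclassified) of class
#'   \code{attribution_scores}.
#' @export
attribution_scores <- function(m, panel = lineage_marker_panel(),
                               params = attribution_params(),
                               which_panel = c("full", "trio")) {
  require_state(m, "log2_tpm1", "attribution_scores")
  which_panel <- match.arg(which_panel)
  sets <- panel[[which_panel]]
  v <- expr_values(m)
  score_one <- function(genes, lab) {
    genes <- panel_in_matrix(m, genes, paste0("attribution_scores[", lab, "]"))
    if (!length(genes)) stop("no ", lab, " panel genes present in matrix")
    x <- v[, genes, drop = FALSE]
    x[x < params$marker_floor] <- 0
    apply(x, 1, max)
  }
  out <- data.frame(cell_id = rownames(v),
                    A = score_one(sets$ADC, "ADC"),
                    S = score_one(sets$SCC, "SCC"),
                    N = score_one(sets$NET, "NET"),
                    stringsAsFactors = FALSE)
  out$unclassified <- out$A == 0 & out$S == 0 & out$N == 0
  rownames(out) <- NULL
  class(out) <- c("attribution_scores", "data.frame")
  out
}

#' Assign cancer subtypes by clustering attribution scores
#'
#' Ward-linkage hierarchical clustering of the (A, S, N) score vectors into
#' \code{n_groups} groups; each group is labelled from its mean score
#' pattern, where a lineage is "positive" when the group mean is at or above
#' the marker floor: one positive lineage gives that single-lineage label;
#' A and S positive give SCC_ADChigh (A > S) or SCChigh_ADC (S > A); N and A
#' give NET_ADC; N and S give NET_SCC; all three give triple_positive; none
#' gives unclassified.
#'
#' @param scores an \code{\link{attribution_scores}} data.frame.
#' @param params an \code{\link{attribution_params}} (uses \code{n_groups}
#'   and \code{marker_floor}).
#' @return list with \code{subtype} (character per cell, named by cell id),
#'   \code{group} (integer group per cell) and \code{group_means}.
#' @export
assign_subtypes <- function(scores, params = attribution_params()) {
  stopifnot(inherits(scores, "attribution_scores"))
  x <- as.matrix(scores[, c("A", "S", "N")])
  rownames(x) <- scores$cell_id
  k <- params$n_groups
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct score vectors; reducing groups")
    k <- n_distinct
  }
  grp <- if (k == 1) rep(1L, nrow(x)) else
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = k)
  gm <- t(vapply(sort(unique(grp)),
                 function(g) colMeans(x[grp == g, , drop = FALSE]),
                 numeric(3)))
  labels <- apply(gm, 1, function(mu) {
    pos <- c("ADC", "SCC", "NET")[mu >= params$marker_floor]
    label_from_positive(pos, mu[1], mu[2])
  })
  subtype <- stats::setNames(labels[grp], scores$cell_id)
  # cells with no marker above the floor are unclassified regardless of group
  subtype[scores$unclassified] <- "unclassified"
  list(subtype = subtype, group = stats::setNames(grp, scores$cell_id),
       group_means = data.frame(group = sort(unique(grp)),
                                A = gm[, 1], S = gm[, 2], N = gm[, 3],
                                label = labels))
}

#' Subtype labels that indicate lineage mixing
#' @export
mixed_subtype_labels <- function()
  c("SCC_ADChigh", "SCChigh_ADC", "NET_ADC", "NET_SCC", "triple_positive")

#' Fraction of mixed-lineage tumor cells per patient
#'
#' @param annotation \code{cell_annotation} with \code{cancer_subtype} set
#'   on tumor epithelial cells.
#' @return data.frame(patient_id, n_tumor_cells, n_mixed, mixed_fraction);
#'   patients with no subtyped tumor epithelial cells are omitted with a
#'   message.
#' @export
mixed_lineage_fraction <- function(annotation) {
  stopifnot(inherits(annotation, "cell_annotation"))
  epi <- is.na(annotation$major_type) | annotation$major_type == "epithelial"
  tum <- annotation[annotation$tissue %in% c("tumor", "lymph_node_metastasis") &
                      epi & !is.na(annotation$cancer_subtype), , drop = FALSE]
  skipped <- setdiff(unique(annotation$patient_id), unique(tum$patient_id))
  if (length(skipped))
    message("patient(s) without subtyped tumor epithelial cells omitted: ",
            paste(skipped, collapse = ", "))
  if (!nrow(tum))
    return(data.frame(patient_id = character(), n_tumor_cells = integer(),
                      n_mixed = integer(), mixed_fraction = numeric()))
  sp <- split(tum$cancer_subtype, tum$patient_id)
  data.frame(patient_id = names(sp),
             n_tumor_cells = vapply(sp, length, integer(1)),
             n_mixed = vapply(sp, function(s)
               sum(s %in% mixed_subtype_labels()), integer(1)),
             mixed_fraction = vapply(sp, function(s)
               mean(s %in% mixed_subtype_labels()), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select archetype cells for each lineage
#'
#' Cells are ranked per lineage by the mean expression of that lineage's
#' classical trio; the top \code{top_n} cells (ties broken by cell id) are
#' the lineage's archetypes. The three lists are selected independently, so
#' a cell may appear in more than one.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state (tumor cells).
#' @param panel a \code{\link{lineage_marker_panel}}.
#' @param top_n cells per lineage (default 50).
#' @return list(ADC, SCC, NET) of cell-id vectors.
#' @export
select_archetype_cells <- function(m, panel = lineage_marker_panel(),
                                   top_n = 50) {
  require_state(m, "log2_tpm1", "select_archetype_cells")
  v <- expr_values(m)
  lapply(panel$trio, function(genes) {
    genes <- panel_in_matrix(m, genes, "select_archetype_cells")
    mu <- rowMeans(v[, genes, drop = FALSE])
    elig <- names(mu)[mu > 0]
    if (length(elig) < top_n)
      warning("only ", length(elig), " eligible cells for a lineage (top_n = ",
              top_n, "); taking all")
    ord <- elig[order(-mu[elig], elig)]
    utils::head(ord, top_n)
  })
}

#' Derive top-DEG lineage signatures from archetype cells
#'
#' Cells appearing in more than one archetype list are removed from all of
#' them (archetypes must be lineage-pure), then one-vs-rest positive markers
#' are computed across the three archetype groups and the top
#' \code{top_n_degs} genes per lineage by adjusted p are returned.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param archetype_cells list(ADC, SCC, NET) from
#'   \code{\link{select_archetype_cells}}.
#' @param de a \code{\link{de_params}} (only_pos is forced TRUE).
#' @param top_n_degs signature size per lineage (default 50).
#' @return list(ADC, SCC, NET) of gene-id vectors (class
#'   \code{lineage_signatures}).
#' @export
lineage_signatures <- function(m, archetype_cells, de = de_params(),
                               top_n_degs = 50) {
  require_state(m, "log2_tpm1", "lineage_signatures")
  all_cells <- unlist(archetype_cells, use.names = FALSE)
  dup <- unique(all_cells[duplicated(all_cells)])
  arch <- lapply(archetype_cells, function(cc) setdiff(cc, dup))
  labels <- rep(names(arch), lengths(arch))
  cells <- unlist(arch, use.names = FALSE)
  sub <- m[match(cells, cell_ids(m)), seq_len(ncol(m$values))]
  de$only_pos <- TRUE
  res <- find_markers(sub, labels, de)
  sig <- lapply(c(ADC = "ADC", SCC = "SCC", NET = "NET"), function(g) {
    rows <- res[res$group == g, , drop = FALSE]
    if (nrow(rows) < top_n_degs)
      warning("only ", nrow(rows), " significant genes for ", g,
              " signature (requested ", top_n_degs, ")")
    utils::head(rows$gene_id, top_n_degs)
  })
  class(sig) <- "lineage_signatures"
  sig
}

#' Ternary lineage scores from signature expression
#'
#' Raw score = sum of log2(TPM+1) over the lineage's signature genes;
#' each lineage's raw scores are min-max scaled to [0, 100] across the
#' supplied cells; the composition is the raw triple normalized to sum 1
#' (undefined for cells with all raw scores zero).
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state (the cells to
#'   score, typically tumor cells).
#' @param signatures a \code{\link{lineage_signatures}} list.
#' @return data.frame(cell_id, A, S, N, comp_a, comp_s, comp_n) with scaled
#'   scores in [0,100] and composition columns NA when undefined.
#' @export
ternary_scores <- function(m, signatures) {
  require_state(m, "log2_tpm1", "ternary_scores")
  if (any(lengths(signatures) == 0)) stop("empty lineage signature")
  v <- expr_values(m)
  raw <- vapply(signatures[c("ADC", "SCC", "NET")], function(genes) {
    genes <- intersect(genes, colnames(v))
    if (!length(genes)) stop("no signature genes present in matrix")
    rowSums(v[, genes, drop = FALSE])
  }, numeric(nrow(v)))
  scale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant raw score across cells; scaled score set to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng) * 100
  }
  scaled <- apply(raw, 2, scale01)
  tot <- rowSums(raw)
  comp <- raw / ifelse(tot > 0, tot, NA)
  out <- data.frame(cell_id = rownames(v), A = scaled[, "ADC"],
                    S = scaled[, "SCC"], N = scaled[, "NET"],
                    comp_a = comp[, "ADC"], comp_s = comp[, "SCC"],
                    comp_n = comp[, "NET"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ternary_scores", "data.frame")
  out
}

#' Apply attribution scoring and subtype assignment to an external matrix
#'
#' Cells with every lineage marker below the floor are dropped (only cells
#' expressing some lineage marker enter the denominator), then attribution
#' scores and subtype labels are computed exactly as for the internal data.
#'
#' @param m \code{expr_matrix} in \code{log2_tpm1} state.
#' @param panel a \code{\link{lineage_marker_panel}}.
#' @param params an \code{\link{attribution_params}}.
#' @param which_panel \code{"full"} or \code{"trio"}.
#' @return list(subtype, scores, n_scored, n_dropped, mixed_fraction).
#' @export
apply_to_external <- function(m, panel = lineage_marker_panel(),
                              params = attribution_params(),
                              which_panel = "trio") {
  sc <- attribution_scores(m, panel, params, which_panel = which_panel)
  keep <- !sc$unclassified
  if (!any(keep)) stop("no cells express any lineage marker above the floor")
  sc_kept <- sc[keep, , drop = FALSE]
  class(sc_kept) <- class(sc)
  asg <- assign_subtypes(sc_kept, params)
  mixed <- mean(asg$subtype %in% mixed_subtype_labels())
  list(subtype = asg$subtype, scores = sc_kept, n_scored = sum(keep),
       n_dropped = sum(!keep), mixed_fraction = mixed)
}
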