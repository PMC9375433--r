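#' Thresholds for mitochondrial variant lineage tracing
#'
#' Presence of a variant in a cell is binarized on allele frequency: carried
#' when AF >= \code{min_af_present}, absent when AF <= \code{max_af_absent}
#' (intermediate AFs count as non-carrier but are not evidence of absence in
#' normals). All thresholds are declared free parameters of the method.
#'
#' @param min_af_present carrier AF threshold (default 0.2).
#' @param max_af_absent absence AF threshold in reference cells
#'   (default 0.05).
#' @param min_tumor_fraction minimum carrier fraction among tumor cells
#'   (default 0.5).
#' @param max_normal_fraction maximum fraction of normal cells with
#'   AF > \code{max_af_absent} (default 0.05).
#' @param min_covered_cells minimum covered (non-missing) cells per group
#'   for a variant to be evaluated (default 10).
#' @export
mito_params <- function(min_af_present = 0.2, max_af_absent = 0.05,
                        min_tumor_fraction = 0.5, max_normal_fraction = 0.05,
                        min_covered_cells = 10) {
  if (max_af_absent >= min_af_present)
    stop("max_af_absent must be < min_af_present")
  structure(list(min_af_present = min_af_present,
                 max_af_absent = max_af_absent,
                 min_tumor_fraction = min_tumor_fraction,
                 max_normal_fraction = max_normal_fraction,
                 min_covered_cells = min_covered_cells),
            class = "mito_params")
}

check_variant_ids <- function(ids) {
  pos <- suppressWarnings(as.integer(sub("_.*$", "", ids)))
  bad <- is.na(pos) | pos < 1 | pos > 16569
  if (any(bad))
    stop("malformed mitochondrial variant id(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  invisible(ids)
}

#' Identify tumor-specific mitochondrial variants
#'
#' A variant is tumor-specific when its carrier fraction (AF >=
#' \code{min_af_present}) among tumor epithelial cells is at least
#' \code{min_tumor_fraction} while at most \code{max_normal_fraction} of
#' normal epithelial cells show AF above \code{max_af_absent}. Variants with
#' fewer than \code{min_covered_cells} covered cells in either group are
#' excluded and counted.
#'
#' @param afm cell x variant allele-frequency matrix (NA = no coverage).
#' @param annotation \code{cell_annotation}; tumor/normal epithelial cells
#'   define the two groups.
#' @param params a \code{\link{mito_params}}.
#' @return list with \code{variants} (data.frame of retained variants and
#'   their carrier fractions), \code{subtype_fractions} (carrier fraction
#'   per retained variant per cancer subtype) and \code{n_low_coverage}.
#' @export
tumor_specific_variants <- function(afm, annotation, params = mito_params()) {
  stopifnot(inherits(annotation, "cell_annotation"))
  check_variant_ids(colnames(afm))
  ann <- annotation[match(rownames(afm), annotation$cell_id), ]
  epi <- is.na(ann$major_type) | ann$major_type == "epithelial"
  tumor <- which(epi & ann$tissue %in% c("tumor", "lymph_node_metastasis"))
  normal <- which(epi & ann$tissue == "normal")
  if (!length(normal)) stop("no normal epithelial cells: no reference for tumor specificity")
  if (!length(tumor)) stop("no tumor epithelial cells in AF matrix")

  carrier_frac <- function(x, idx, thr) {
    x <- x[idx]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(x >= thr)
  }
  cov_t <- colSums(!is.na(afm[tumor, , drop = FALSE]))
  cov_n <- colSums(!is.na(afm[normal, , drop = FALSE]))
  covered <- cov_t >= params$min_covered_cells & cov_n >= params$min_covered_cells
  n_low <- sum(!covered)
  res <- data.frame(variant_id = colnames(afm)[covered],
                    tumor_carrier_fraction = NA_real_,
                    normal_above_absent = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    x <- afm[, res$variant_id[i]]
    res$tumor_carrier_fraction[i] <-
      carrier_frac(x, tumor, params$min_af_present)
    xn <- x[normal]; xn <- xn[!is.na(xn)]
    res$normal_above_absent[i] <- mean(xn > params$max_af_absent)
  }
  keep <- res$tumor_carrier_fraction >= params$min_tumor_fraction &
    res$normal_above_absent <= params$max_normal_fraction
  retained <- res[keep, , drop = FALSE]
  rownames(retained) <- NULL

  subty <- ann$cancer_subtype
  st_frac <- NULL
  if (nrow(retained) && any(!is.na(subty))) {
    sts <- sort(unique(subty[!is.na(subty)]))
    st_frac <- do.call(rbind, lapply(retained$variant_id, function(vid) {
      x <- afm[, vid]
      data.frame(variant_id = vid, cancer_subtype = sts,
                 n_covered = vapply(sts, function(s)
                   sum(!is.na(x) & subty %in% s), integer(1)),
                 carrier_fraction = vapply(sts, function(s)
                   carrier_frac(x, which(subty %in% s),
                                params$min_af_present), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(st_frac) <- NULL
  }
  list(variants = retained, subtype_fractions = st_frac,
       n_low_coverage = n_low)
}

#' Do the cancer subtypes share the tumor-specific variants?
#'
#' Summarizes carrier fractions per (variant, subtype) and flags the result
#' as consistent with a common clonal ancestor when every retained variant
#' reaches \code{min_tumor_fraction} in every subtype with at least
#' \code{min_covered_cells} covered cells; subtypes below that coverage are
#' excluded from the flag and listed.
#'
#' @param variants output of \code{\link{tumor_specific_variants}}.
#' @param params the same \code{\link{mito_params}}.
#' @return list(table, common_ancestor_consistent, excluded_subtypes).
#' @export
shared_ancestry_summary <- function(variants, params = mito_params()) {
  tab <- variants$subtype_fractions
  if (is.null(tab) || !nrow(variants$variants))
    stop("no tumor-specific variants (or no subtype labels) to summarize")
  if (length(unique(tab$cancer_subtype)) < 2)
    stop("need >= 2 cancer subtypes")
  eval_tab <- tab[tab$n_covered >= params$min_covered_cells, , drop = FALSE]
  excluded <- setdiff(unique(tab$cancer_subtype),
                      unique(eval_tab$cancer_subtype))
  if (length(excluded))
    message("subtype(s) below coverage excluded from the ancestry flag: ",
            paste(excluded, collapse = ", "))
  flag <- all(eval_tab$carrier_fraction >= params$min_tumor_fraction)
  list(table = tab, common_ancestor_consistent = flag,
       excluded_subtypes = excluded)
}
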