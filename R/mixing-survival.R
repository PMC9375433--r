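#' Parameters for the bulk lineage-mixing score
#'
#' @param c proportionality constant of the mixing score (default 1; under
#'   c = 1 a score of 1 corresponds to a dominant lineage fraction of 0.5).
#' @param split_adc score threshold splitting ADC cohorts (default 1).
#' @param split_scc score threshold splitting SCC cohorts (default 1.33).
#' @export
mixing_params <- function(c = 1, split_adc = 1, split_scc = 1.33) {
  stopifnot(c > 0)
  structure(list(c = c, split_adc = split_adc, split_scc = split_scc),
            class = "mixing_params")
}

#' Normalized lineage composition of bulk samples
#'
#' Raw lineage score = total expression over the lineage's signature genes;
#' the three raw scores are normalized to sum to 1. Samples with zero total
#' signature expression are excluded and reported.
#'
#' @param expr_table numeric matrix or data.frame, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param signatures list(ADC, SCC, NET) of gene ids (e.g. a
#'   \code{\link{lineage_signatures}} object or any user-supplied sets).
#' @return data.frame(sample_id, A, S, N) plus attribute
#'   \code{"excluded"} listing zero-total samples.
#' @export
bulk_lineage_scores <- function(expr_table, signatures) {
  x <- as.matrix(expr_table)
  raw <- vapply(signatures[c("ADC", "SCC", "NET")], function(genes) {
    genes <- intersect(genes, rownames(x))
    if (!length(genes)) stop("no signature genes present in expression table")
    colSums(x[genes, , drop = FALSE])
  }, numeric(ncol(x)))
  tot <- rowSums(raw)
  bad <- tot <= 0
  if (any(bad))
    warning(sum(bad), " sample(s) with zero signature expression excluded")
  comp <- raw[!bad, , drop = FALSE] / tot[!bad]
  out <- data.frame(sample_id = colnames(x)[!bad], A = comp[, "ADC"],
                    S = comp[, "SCC"], N = comp[, "NET"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- colnames(x)[bad]
  out
}

#' Lineage-mixing score
#'
#' \code{score = c * (1 - max(A, S, N)) / max(A, S, N)} for a normalized
#' composition; 0 for a pure sample, 2c at perfect three-way mixing.
#'
#' @param composition data.frame or matrix with columns A, S, N (each row a
#'   normalized composition), or a numeric vector of length 3.
#' @param params a \code{\link{mixing_params}}.
#' @return numeric score(s) in [0, 2c].
#' @export
mixing_score <- function(composition, params = mixing_params()) {
  if (is.numeric(composition) && is.null(dim(composition)))
    composition <- matrix(composition, nrow = 1,
                          dimnames = list(NULL, c("A", "S", "N")))
  comp <- as.matrix(as.data.frame(composition)[, c("A", "S", "N")])
  if (any(comp < 0)) stop("lineage scores must be nonnegative")
  sums <- rowSums(comp)
  if (any(abs(sums - 1) > 1e-9)) stop("composition rows must sum to 1")
  mx <- apply(comp, 1, max)
  params$c * (1 - mx) / mx
}

#' Split a cohort into high- and low-mixing groups
#'
#' ADC samples split at \code{split_adc}, SCC samples at \code{split_scc};
#' a score exactly at the threshold goes to the low group.
#'
#' @param cohort data.frame with columns \code{histology} ("ADC"/"SCC") and
#'   \code{score}.
#' @param params a \code{\link{mixing_params}}.
#' @return factor ("low"/"high") per sample, plus a message when a group is
#'   empty.
#' @export
split_cohort <- function(cohort, params = mixing_params()) {
  stopifnot(all(c("histology", "score") %in% names(cohort)))
  thr <- ifelse(cohort$histology == "ADC", params$split_adc,
                params$split_scc)
  grp <- factor(ifelse(cohort$score > thr, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0))
    warning("empty ", names(which(table(grp) == 0))[1],
            "-score group; survival comparison not meaningful")
  grp
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times nonnegative event/censoring times.
#' @param events 1 = event, 0 = right-censored.
#' @return data.frame of class \code{km_fit}: one row per distinct event
#'   time with n_risk, n_event, n_censor and the survival estimate.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), all(events %in% 0:1))
  if (any(times < 0)) stop("negative survival time")
  ord <- order(times, -events)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times[events == 1])
  n <- length(times)
  surv <- 1
  rows <- lapply(ut, function(t) {
    n_risk <- sum(times >= t)
    n_event <- sum(times == t & events == 1)
    n_censor <- sum(times == t & events == 0)
    surv <<- surv * (1 - n_event / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), survival = numeric())
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Median survival time from a Kaplan-Meier fit
#'
#' First event time at which the survival estimate drops to 0.5 or below;
#' NA when the curve never reaches 0.5.
#'
#' @param fit a \code{km_fit}.
#' @export
km_median <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  idx <- which(fit$survival <= 0.5)
  if (!length(idx)) return(NA_real_)
  fit$time[idx[1]]
}

#' @export
plot.km_fit <- function(x, add = FALSE, ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$survival, each = 2)[-2 * nrow(x)])
  if (add) graphics::lines(t, s, ...) else
    graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = "time",
                   ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Classical log-rank chi-square with 1 degree of freedom: at each distinct
#' event time the observed events in group 1 are compared with the
#' hypergeometric expectation and variance given the at-risk sets; the
#' p-value is the chi-square upper tail.
#'
#' @param groups two-level group label per subject.
#' @param times event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return list(statistic, p_value, observed, expected) with observed and
#'   expected event counts per group.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("log-rank test requires exactly 2 groups")
  stopifnot(length(groups) == length(times), length(times) == length(events))
  g1 <- groups == levels(groups)[1]
  ut <- sort(unique(times[events == 1]))
  if (!length(ut)) stop("no events; log-rank statistic undefined")
  O <- 0; E <- 0; V <- 0
  O2 <- 0; E2 <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    O2 <- O2 + (d - d1)
    E2 <- E2 + d * (n - n1) / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) {
    # identical groups or no variance: no evidence against the null
    stat <- 0; p <- 1
  } else {
    stat <- (O - E)^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p,
       observed = stats::setNames(c(O, O2), levels(groups)),
       expected = stats::setNames(c(E, E2), levels(groups)))
}

#' Mixing scores stratified by a mutation flag
#'
#' Within each histology, compares mixing scores between mutant and
#' wild-type samples with a two-sided Wilcoxon rank-sum test and reports
#' the direction of the median difference. Strata with an empty side are
#' skipped with a note.
#'
#' @param cohort data.frame with \code{histology} and \code{score}.
#' @param mutation_flags logical/0-1 flag per sample (TRUE = mutant).
#' @return data.frame(histology, n_mutant, n_wildtype, median_mutant,
#'   median_wildtype, direction, p_value).
#' @export
mutation_stratified_mixing <- function(cohort, mutation_flags) {
  stopifnot(nrow(cohort) == length(mutation_flags))
  flags <- as.logical(mutation_flags)
  out <- lapply(sort(unique(cohort$histology)), function(h) {
    sel <- cohort$histology == h
    mu <- cohort$score[sel & flags]; wt <- cohort$score[sel & !flags]
    if (!length(mu) || !length(wt)) {
      message("stratum ", h, " has an empty side; skipped")
      return(NULL)
    }
    p <- suppressWarnings(stats::wilcox.test(mu, wt)$p.value)
    data.frame(histology = h, n_mutant = length(mu), n_wildtype = length(wt),
               median_mutant = stats::median(mu),
               median_wildtype = stats::median(wt),
               direction = ifelse(stats::median(mu) > stats::median(wt),
                                  "mutant_higher",
                                  ifelse(stats::median(mu) <
                                           stats::median(wt),
                                         "wildtype_higher", "equal")),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
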