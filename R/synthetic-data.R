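#' Configuration for the synthetic NSCLC single-cell simulator
#'
#' The simulator emulates the data structure the analysis pipeline assumes:
#' a plate-based single-cell study of lung tumors with matched normal tissue,
#' three cancer lineage programs (adenocarcinoma ADC, squamous SCC,
#' neuroendocrine NET), a planted fraction of mixed-lineage tumor cells,
#' stromal cell types, clonal chromosome-scale CNV segments, clonal
#' mitochondrial variants, and a bulk cohort whose hazard depends on the
#' lineage-mixing score.
#'
#' Expression means are specified on the log2(TPM+1) scale; counts are drawn
#' from a negative binomial on the linear scale and a set of housekeeping
#' genes fills each cell's expected transcriptome to one million so that the
#' TPM normalization downstream lands marker genes near their specified
#' log-scale means.
#'
#' @param n_patients number of patients (each contributes a tumor and a
#'   matched normal tissue).
#' @param cells_per_patient cells per patient per tissue.
#' @param stromal_fraction named fractions for the five stromal types;
#'   epithelial cells take the remainder.
#' @param mixed_lineage_fraction fraction of tumor epithelial cells with a
#'   mixed (>= 2 lineage) composition.
#' @param composition_mode \code{"dirichlet"} draws mixed compositions from
#'   a Dirichlet over the active lineages (realistic, fuzzy boundaries);
#'   \code{"archetypes"} plants the five well-separated subtype archetypes
#'   (pure ADC/SCC/NET, A-dominant and S-dominant ADC+SCC mixtures, an
#'   ADC+NET mixture, and the symmetric triple) with fixed weights.
#' @param lineage_probs sampling weights for the dominant lineage.
#' @param marker_high_mean,background_mean expression means, log2(TPM+1).
#' @param n_background_genes background genes (>= 1000 for realistic panels).
#' @param n_program_genes lineage-program genes per lineage beyond the
#'   marker panel (these are what signature discovery should recover).
#' @param library_size expected total counts per cell.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param cnv_segments data.frame(chromosome, start, end, fold_change) of
#'   clonal segments carried by all tumor cells; coordinates 0-based
#'   half-open on the synthetic genome (5 chromosomes x 100 Mb).
#' @param mito_clone_variants data.frame(variant_id, tumor_af, normal_af) of
#'   clonal mitochondrial variants carried by all tumor epithelial cells.
#' @param n_mito_noise_variants sporadic low-heteroplasmy variants.
#' @param wgs_depth reads per sample in the simulated bulk WGS table.
#' @param survival list(n_samples, baseline_hazard, hazard_ratio,
#'   censoring_rate) for the bulk cohort; hazard_ratio is the multiplicative
#'   hazard per unit of mixing score.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(
    n_patients = 4,
    cells_per_patient = 150,
    stromal_fraction = c(fibroblast = 0.05, B = 0.05, T = 0.15,
                         myeloid = 0.10, mast = 0.02),
    mixed_lineage_fraction = 0.7,
    composition_mode = c("dirichlet", "archetypes"),
    lineage_probs = c(ADC = 0.6, SCC = 0.25, NET = 0.15),
    marker_high_mean = 8,
    background_mean = 1,
    n_background_genes = 1000,
    n_program_genes = 60,
    library_size = 2e5,
    dispersion = 0.5,
    cnv_segments = data.frame(
      chromosome = c("chr1", "chr3"),
      start = c(0, 5e7), end = c(5e7, 1e8),
      fold_change = c(2, 0.5)),
    mito_clone_variants = data.frame(
      variant_id = c("2645_G", "13226_G"),
      tumor_af = c(0.9, 0.9), normal_af = c(0.01, 0.01)),
    n_mito_noise_variants = 20,
    wgs_depth = 2e5,
    survival = list(n_samples = 200, baseline_hazard = 0.02,
                    hazard_ratio = 3, censoring_rate = 0.3),
    seed = 1L) {
  stopifnot(n_patients >= 1, cells_per_patient >= 1,
            all(stromal_fraction >= 0), all(stromal_fraction <= 1),
            mixed_lineage_fraction >= 0, mixed_lineage_fraction <= 1,
            dispersion >= 0, n_background_genes >= 1, library_size > 0)
  if (sum(stromal_fraction) >= 1)
    stop("stromal fractions must leave a positive epithelial fraction")
  if (nrow(cnv_segments) > 0 && any(cnv_segments$fold_change <= 0))
    stop("CNV fold changes must be > 0")
  if (!is.null(survival$censoring_rate) &&
      (survival$censoring_rate < 0 || survival$censoring_rate > 1))
    stop("censoring rate must be in [0,1]")
  composition_mode <- match.arg(composition_mode)
  cfg <- list(n_patients = n_patients, cells_per_patient = cells_per_patient,
              stromal_fraction = stromal_fraction,
              mixed_lineage_fraction = mixed_lineage_fraction,
              composition_mode = composition_mode,
              lineage_probs = lineage_probs / sum(lineage_probs),
              marker_high_mean = marker_high_mean,
              background_mean = background_mean,
              n_background_genes = n_background_genes,
              n_program_genes = n_program_genes,
              library_size = library_size, dispersion = dispersion,
              cnv_segments = cnv_segments,
              mito_clone_variants = mito_clone_variants,
              n_mito_noise_variants = n_mito_noise_variants,
              wgs_depth = wgs_depth, survival = survival,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# synthetic genome: 5 chromosomes x 100 Mb
sim_chromosomes <- function() {
  stats::setNames(rep(1e8, 5), paste0("chr", 1:5))
}

# symmetric-ish Dirichlet via gamma draws
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

major_type_markers_default <- c(epithelial = "EPCAM", fibroblast = "THY1",
                                B = "CD79A", T = "CD3D", myeloid = "CD68",
                                mast = "KIT")

# gene universe for the simulator: lineage panels, lineage program genes
# (anchored by CEACAM6/TRIM29/TUBB3), major-type markers, housekeeping
# filler, and background genes, laid out round-robin over the chromosomes
sim_gene_table <- function(config) {
  panel <- lineage_marker_panel()
  anchors <- list(ADC = "CEACAM6", SCC = "TRIM29", NET = "TUBB3")
  prog <- lapply(c("ADC", "SCC", "NET"), function(l) {
    n_extra <- max(config$n_program_genes - 1, 0)
    c(anchors[[l]], sprintf("%s_PROG%03d", l, seq_len(n_extra)))
  })
  names(prog) <- c("ADC", "SCC", "NET")
  hk <- sprintf("HK%02d", 1:50)
  bg <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(unlist(panel$full, use.names = FALSE), unlist(prog, use.names = FALSE),
             unname(major_type_markers_default), hk, bg)
  stopifnot(!anyDuplicated(genes))
  # scatter gene roles over the genome so marker/program genes are not
  # positionally clustered (uses the caller's seeded RNG; deterministic)
  genes <- sample(genes)
  chroms <- sim_chromosomes()
  idx <- seq_along(genes)
  chr <- names(chroms)[((idx - 1L) %% length(chroms)) + 1L]
  pos_rank <- (idx - 1L) %/% length(chroms)
  n_per_chr <- table(chr)[chr]
  start <- floor((pos_rank + 0.5) / as.numeric(n_per_chr) * 1e8)
  ann <- gene_annotation(data.frame(
    gene_id = genes, chromosome = chr,
    start = start, end = start + 1000L, strand = "+",
    stringsAsFactors = FALSE))
  list(annotation = ann, panel = panel, program = prog, housekeeping = hk,
       background = bg)
}

# draw one tumor cell's lineage composition; mixed cells use a Dirichlet
# (concentration 0.8) over >= 2 active lineages with every active weight
# kept above 0.2 so planted mixing clears the log2(TPM+1) >= 5 marker floor
draw_composition <- function(config) {
  lins <- c("ADC", "SCC", "NET")
  w <- stats::setNames(numeric(3), lins)
  mixed <- stats::runif(1) < config$mixed_lineage_fraction
  if (config$composition_mode == "archetypes") {
    # the five planted groups: pure ADC and four well-separated mixtures
    if (mixed) {
      arch <- list(c(0.72, 0.28, 0), c(0.28, 0.72, 0), c(0.72, 0, 0.28),
                   c(1, 1, 1) / 3)
      w[] <- arch[[sample(4, 1)]]
    } else {
      w["ADC"] <- 1
    }
    return(w)
  }
  if (mixed) {
    k <- if (stats::runif(1) < 0.7) 2L else 3L
    active <- sample(lins, k, prob = config$lineage_probs)
    repeat {
      ww <- rdirichlet1(rep(0.8, k))
      if (min(ww) >= 0.2) break
    }
    w[active] <- ww
  } else {
    w[sample(lins, 1, prob = config$lineage_probs)] <- 1
  }
  w
}

subtype_from_weights <- function(w) {
  active <- names(w)[w > 0]
  label_from_positive(active, w["ADC"], w["SCC"])
}

# shared labelling rule: which lineages are "positive" -> subtype name
label_from_positive <- function(active, a, s) {
  key <- paste(sort(active), collapse = "+")
  switch(key,
         "ADC" = "ADC", "SCC" = "SCC", "NET" = "NET",
         "ADC+SCC" = if (a > s) "SCC_ADChigh" else "SCChigh_ADC",
         "ADC+NET" = "NET_ADC",
         "NET+SCC" = "NET_SCC",
         "ADC+NET+SCC" = "triple_positive",
         "unclassified")
}

#' Simulate a single-cell NSCLC dataset with planted ground truth
#'
#' Generates a cell x gene count matrix, cell annotation, gene annotation,
#' a mitochondrial allele-frequency matrix, and the ground truth used to
#' validate the pipeline. Tumor epithelial cells carry the configured CNV
#' segments (expression means multiplied by the fold change inside each
#' segment) and the clonal mitochondrial variants; normal epithelial cells
#' carry neither.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{expression} (counts \code{expr_matrix}),
#'   \code{cells} (\code{cell_annotation}), \code{genes}
#'   (\code{gene_annotation}), \code{mito_afm} (cell x variant AF matrix),
#'   and \code{truth} (per-cell types, lineage weights, clone membership,
#'   plus the CNV segment table).
#' @export
simulate_single_cell_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gt <- sim_gene_table(config)
  ann <- gt$annotation
  genes <- ann$gene_id
  n_genes <- length(genes)

  types <- c("epithelial", names(config$stromal_fraction))
  type_probs <- c(1 - sum(config$stromal_fraction), config$stromal_fraction)

  # base expected TPM on the linear scale
  t_bg <- 2^config$background_mean - 1
  t_hi <- 2^config$marker_high_mean - 1
  # program genes are moderately (not marker-level) elevated: ~3 log2 units
  # over background, comfortably past the DE fold-change screen
  t_prog <- 2^(config$background_mean + 3) - 1
  base <- stats::setNames(rep(t_bg, n_genes), genes)
  hk_idx <- genes %in% gt$housekeeping

  # lineage program vectors: panel markers and the named anchor gene at the
  # high mean, remaining program genes slightly lower
  lin_extra <- lapply(c("ADC", "SCC", "NET"), function(l) {
    v <- numeric(n_genes)
    v[genes %in% gt$program[[l]]] <- t_prog - t_bg
    v[genes %in% c(gt$panel$full[[l]], gt$program[[l]][1])] <- t_hi - t_bg
    v
  })
  names(lin_extra) <- c("ADC", "SCC", "NET")

  cells <- list(); truth <- list(); means <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (tissue in c("tumor", "normal")) {
      n <- config$cells_per_patient
      ct <- sample(types, n, replace = TRUE, prob = type_probs)
      for (i in seq_len(n)) {
        cid <- sprintf("%s_%s_c%04d", pid, tissue, i)
        mu <- base
        mu[genes == major_type_markers_default[[ct[i]]]] <- t_hi
        w <- stats::setNames(c(NA_real_, NA_real_, NA_real_), c("ADC", "SCC", "NET"))
        is_cancer <- tissue == "tumor" && ct[i] == "epithelial"
        if (is_cancer) {
          w <- draw_composition(config)
          mu <- mu + w[["ADC"]] * lin_extra$ADC + w[["SCC"]] * lin_extra$SCC +
            w[["NET"]] * lin_extra$NET
        }
        # housekeeping filler brings the expected transcriptome to 1e6 TPM
        mu[hk_idx] <- (1e6 - sum(mu[!hk_idx])) / sum(hk_idx)
        if (is_cancer && nrow(config$cnv_segments) > 0) {
          for (s in seq_len(nrow(config$cnv_segments))) {
            seg <- config$cnv_segments[s, ]
            in_seg <- ann$chromosome == seg$chromosome &
              ann$start >= seg$start & ann$start < seg$end
            mu[in_seg] <- mu[in_seg] * seg$fold_change
          }
        }
        means[[cid]] <- mu
        cells[[cid]] <- data.frame(cell_id = cid, patient_id = pid,
                                   tissue = tissue, stringsAsFactors = FALSE)
        truth[[cid]] <- data.frame(
          cell_id = cid, patient_id = pid, tissue = tissue,
          true_major_type = ct[i],
          w_ADC = w[["ADC"]], w_SCC = w[["SCC"]], w_NET = w[["NET"]],
          true_subtype = if (is_cancer) subtype_from_weights(w) else NA_character_,
          mito_clone = is_cancer, stringsAsFactors = FALSE)
      }
    }
  }
  mu_mat <- do.call(rbind, means)           # cells x genes, expected TPM
  colnames(mu_mat) <- genes
  lam <- mu_mat * (config$library_size / 1e6)
  counts <- matrix(0L, nrow(lam), ncol(lam), dimnames = dimnames(lam))
  if (config$dispersion > 0) {
    counts[] <- stats::rnbinom(length(lam), mu = as.vector(lam),
                               size = 1 / config$dispersion)
  } else {
    counts[] <- stats::rpois(length(lam), as.vector(lam))
  }

  truth_df <- do.call(rbind, truth); rownames(truth_df) <- NULL
  cells_df <- cell_annotation(do.call(rbind, cells))
  rownames(cells_df) <- NULL
  afm <- simulate_mito_afm(config, truth_df)
  list(expression = expression_matrix(counts, "counts"),
       cells = cells_df, genes = ann, mito_afm = afm,
       truth = list(cells = truth_df, cnv_segments = config$cnv_segments))
}

#' Simulate a mitochondrial allele-frequency matrix
#'
#' Generates a cell x variant AF matrix: the configured clonal variants with
#' Beta noise around their tumor AF in clone members (and around their
#' normal AF elsewhere), sporadic low-heteroplasmy noise variants, two
#' germline-like variants near AF 1 in every cell, and ~5\% missing entries
#' emulating insufficient coverage.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param cells data.frame with \code{cell_id} and logical
#'   \code{mito_clone} (clone membership, normally all tumor epithelial
#'   cells).
#' @return numeric matrix, cells x variants, AF in [0,1] or NA.
#' @export
simulate_mito_afm <- function(config, cells) {
  stopifnot(inherits(config, "sim_config"),
            all(c("cell_id", "mito_clone") %in% names(cells)))
  set.seed(config$seed + 3L)
  truth_df <- cells
  n <- nrow(truth_df)
  beta_around <- function(af, n, conc = 50) {
    af <- pmin(pmax(af, 1e-4), 1 - 1e-4)
    stats::rbeta(n, af * conc, (1 - af) * conc)
  }
  cols <- list()
  cv <- config$mito_clone_variants
  in_clone <- truth_df$mito_clone
  for (i in seq_len(nrow(cv))) {
    af <- numeric(n)
    af[in_clone] <- beta_around(cv$tumor_af[i], sum(in_clone))
    af[!in_clone] <- beta_around(cv$normal_af[i], sum(!in_clone))
    cols[[cv$variant_id[i]]] <- af
  }
  if (config$n_mito_noise_variants > 0) {
    pos <- sample(setdiff(1:16569, as.integer(sub("_.*", "", cv$variant_id))),
                  config$n_mito_noise_variants)
    for (p in pos)
      cols[[sprintf("%d_%s", p, sample(c("A", "C", "G", "T"), 1))]] <-
        stats::rbeta(n, 0.2, 20)
  }
  for (p in c(263L, 8860L))
    cols[[sprintf("%d_G", p)]] <- beta_around(0.99, n)
  afm <- do.call(cbind, cols)
  rownames(afm) <- truth_df$cell_id
  afm[stats::runif(length(afm)) < 0.05] <- NA
  afm
}

#' Simulate a bulk cohort with survival driven by lineage mixing
#'
#' Each sample's (A, S, N) composition is drawn from a two-component
#' Dirichlet scheme (a dominant-lineage component, concentration (6,1,1)
#' permuted, and a mixed component, symmetric concentration 2), the
#' lineage-mixing score is computed as \code{(1 - max)/max}, and event times
#' are exponential with hazard \code{baseline_hazard *
#' hazard_ratio^score}. Censored samples get a uniform time before their
#' event.
#'
#' @param config a \code{\link{simulation_config}}; the \code{survival}
#'   element supplies cohort size and hazard parameters.
#' @return data.frame of class \code{survival_cohort} with columns
#'   sample_id, histology, A, S, N, score, time, event, endpoint.
#' @export
simulate_bulk_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  sv <- config$survival
  if (sv$hazard_ratio <= 0) stop("hazard ratio must be > 0")
  if (sv$n_samples < 20) stop("bulk cohort needs n_samples >= 20")
  set.seed(config$seed + 1L)
  n <- sv$n_samples
  comp <- t(vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.5) {
      dom <- sample(1:3, 1, prob = config$lineage_probs)
      alpha <- c(1, 1, 1); alpha[dom] <- 6
      rdirichlet1(alpha)
    } else {
      rdirichlet1(c(2, 2, 2))
    }
  }, numeric(3)))
  colnames(comp) <- c("A", "S", "N")
  score <- (1 - apply(comp, 1, max)) / apply(comp, 1, max)
  hazard <- sv$baseline_hazard * sv$hazard_ratio^score
  time <- stats::rexp(n, rate = hazard)
  event <- rep(1L, n)
  cens <- stats::runif(n) < sv$censoring_rate
  time[cens] <- stats::runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    histology = ifelse(comp[, "A"] >= comp[, "S"], "ADC", "SCC"),
                    A = comp[, "A"], S = comp[, "S"], N = comp[, "N"],
                    score = score, time = time, event = event,
                    endpoint = "OS", stringsAsFactors = FALSE)
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Simulate a bulk WGS read-position table
#'
#' Reads for a tumor and a matched normal sample are multinomially assigned
#' to 10-Mb windows with weights proportional to window length times the
#' window's copy state (the configured fold change for tumor windows inside
#' CNV segments, 1 elsewhere and everywhere in the normal), then given
#' uniform positions within their window.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param window_bp window size used to lay out copy states.
#' @return data.frame(chromosome, position, sample) with
#'   \code{config$wgs_depth} reads per sample.
#' @export
simulate_wgs_read_table <- function(config = simulation_config(),
                                    window_bp = 1e7) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  chroms <- sim_chromosomes()
  win <- do.call(rbind, lapply(names(chroms), function(ch) {
    starts <- seq(0, chroms[[ch]] - 1, by = window_bp)
    data.frame(chromosome = ch, start = starts,
               end = pmin(starts + window_bp, chroms[[ch]]),
               stringsAsFactors = FALSE)
  }))
  state <- rep(1, nrow(win))
  if (nrow(config$cnv_segments) > 0) {
    for (s in seq_len(nrow(config$cnv_segments))) {
      seg <- config$cnv_segments[s, ]
      # a window takes a segment's state when its midpoint is inside
      mid <- (win$start + win$end) / 2
      hit <- win$chromosome == seg$chromosome & mid >= seg$start & mid < seg$end
      state[hit] <- state[hit] * seg$fold_change
    }
  }
  draw_sample <- function(weights, label) {
    k <- as.vector(stats::rmultinom(1, config$wgs_depth,
                                    weights * (win$end - win$start)))
    idx <- rep(seq_len(nrow(win)), k)
    data.frame(chromosome = win$chromosome[idx],
               position = floor(stats::runif(length(idx), win$start[idx],
                                             win$end[idx])),
               sample = label, stringsAsFactors = FALSE)
  }
  rbind(draw_sample(state, "tumor"), draw_sample(rep(1, nrow(win)), "normal"))
}
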