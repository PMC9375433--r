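# fixtures built in code; no data files

# wrap a plain matrix as a log2(TPM+1)-state expr_matrix
log_expr <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("cell%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("g%03d", seq_len(ncol(v)))
  expression_matrix(v, "log2_tpm1")
}

counts_expr <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("cell%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("g%03d", seq_len(ncol(v)))
  expression_matrix(v, "counts")
}

# adjusted Rand index (closed form over the contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small simulated dataset shared by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_patients = 2, cells_per_patient = 150,
                               seed = 401)
      cache <<- simulate_single_cell_dataset(cfg)
    }
    cache
  }
})

# epithelial log-matrix + annotation + truth from a simulated dataset
epithelial_view <- function(sim) {
  m <- log_transform(tpm_normalize(sim$expression))
  tr <- sim$truth$cells
  epi <- tr$cell_id[tr$true_major_type == "epithelial"]
  list(m = m[match(epi, cell_ids(m)), seq_len(ncol(m))],
       ann = cell_annotation(sim$cells[sim$cells$cell_id %in% epi, ]),
       truth = tr[match(epi, tr$cell_id), ])
}
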