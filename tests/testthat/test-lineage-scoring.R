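panel_fixture <- function(values) {
  genes <- unique(unlist(lineage_marker_panel()$full, use.names = FALSE))
  v <- matrix(0, nrow(values), length(genes),
              dimnames = list(rownames(values), genes))
  v[, colnames(values)] <- values
  log_expr(v)
}

test_that("attribution scores floor sub-threshold markers and take the max", {
  v <- rbind(c1 = c(`NKX2-1` = 6, TP63 = 0, SYP = 0),
             c2 = c(`NKX2-1` = 4.9, TP63 = 0, SYP = 0),
             c3 = c(`NKX2-1` = 0, TP63 = 0, SYP = 0))
  v <- cbind(v, KRT7 = c(0, 0, 7), KRT5 = c(0, 0, 6), SYP2 = 0)
  colnames(v)[6] <- "CHGB"; v["c3", "CHGB"] <- 5.5
  sc <- attribution_scores(panel_fixture(v))
  expect_equal(sc[sc$cell_id == "c1", c("A", "S", "N")],
               data.frame(A = 6, S = 0, N = 0), ignore_attr = TRUE)
  # 4.9 is below the floor of 5: unclassified
  expect_true(sc$unclassified[sc$cell_id == "c2"])
  expect_equal(unlist(sc[sc$cell_id == "c3", c("A", "S", "N")]),
               c(A = 7, S = 6, N = 5.5), ignore_attr = TRUE)
})

test_that("attribution equals a brute-force max-loop oracle on random fixtures", {
  panel <- lineage_marker_panel()
  set.seed(10)
  for (rep in 1:5) {
    genes <- sample(unlist(panel$full, use.names = FALSE), 12)
    v <- matrix(runif(8 * 12, 0, 9), 8, 12,
                dimnames = list(sprintf("c%d", 1:8), genes))
    sc <- suppressWarnings(attribution_scores(log_expr(v)))
    oracle <- function(cell, lin) {
      best <- 0
      for (g in intersect(panel$full[[lin]], genes)) {
        x <- v[cell, g]
        if (x >= 5 && x > best) best <- x
      }
      best
    }
    for (cell in rownames(v)) {
      row <- sc[sc$cell_id == cell, ]
      expect_equal(row$A, oracle(cell, "ADC"))
      expect_equal(row$S, oracle(cell, "SCC"))
      expect_equal(row$N, oracle(cell, "NET"))
    }
  }
})

test_that("raising the marker floor never makes a cell more mixed", {
  set.seed(11)
  genes <- unlist(lineage_marker_panel()$full, use.names = FALSE)
  v <- matrix(runif(60 * length(genes), 0, 9), 60, length(genes),
              dimnames = list(sprintf("c%02d", 1:60), genes))
  n_active <- function(floor) {
    sc <- attribution_scores(log_expr(v),
                             params = attribution_params(marker_floor = floor))
    rowSums(sc[, c("A", "S", "N")] > 0)
  }
  expect_true(all(n_active(6) <= n_active(5)))
  expect_true(all(n_active(8) <= n_active(6)))
})

test_that("subtype groups are labelled from their mean score pattern", {
  mk <- function(a, s, n, n_cells, prefix) {
    v <- matrix(rep(c(a, s, n), each = n_cells), n_cells, 3,
                dimnames = list(sprintf("%s%02d", prefix, seq_len(n_cells)),
                                c("NKX2-1", "TP63", "CHGB")))
    v + matrix(runif(n_cells * 3, -0.2, 0.2), n_cells, 3)
  }
  set.seed(12)
  v <- rbind(mk(8, 0, 0, 20, "a"),   # pure ADC
             mk(6, 7, 0, 20, "b"),   # S > A
             mk(7.5, 5.5, 0, 20, "c"),  # A > S
             mk(6, 0, 7, 20, "d"),   # A + N
             mk(7, 7, 7, 20, "e"))   # all three
  v[v < 0] <- 0
  sc <- attribution_scores(panel_fixture(v))
  asg <- assign_subtypes(sc, attribution_params(n_groups = 5))
  expect_identical(unname(asg$subtype["a01"]), "ADC")
  expect_identical(unname(asg$subtype["b01"]), "SCChigh_ADC")
  expect_identical(unname(asg$subtype["c01"]), "SCC_ADChigh")
  expect_identical(unname(asg$subtype["d01"]), "NET_ADC")
  expect_identical(unname(asg$subtype["e01"]), "triple_positive")

  # degenerate: one archetype only, fewer distinct vectors than groups
  v1 <- mk(8, 0, 0, 10, "z"); v1[v1 < 0] <- 0
  sc1 <- attribution_scores(panel_fixture(v1))
  expect_warning(asg1 <- assign_subtypes(sc1, attribution_params(n_groups = 50)),
                 "reducing")
  expect_true(all(asg1$subtype == "ADC"))
})

test_that("mixed fractions count mixed subtypes among tumor epithelial cells", {
  ann <- cell_annotation(data.frame(
    cell_id = sprintf("c%03d", 1:100), patient_id = rep(c("P1", "P2"), 50),
    tissue = "tumor", major_type = "epithelial",
    cancer_subtype = c(rep("ADC", 60), rep("triple_positive", 40))))
  mf <- mixed_lineage_fraction(ann)
  expect_equal(sum(mf$n_mixed) / sum(mf$n_tumor_cells), 0.4)
  all_adc <- ann; all_adc$cancer_subtype <- "ADC"
  expect_true(all(mixed_lineage_fraction(cell_annotation(all_adc))$mixed_fraction == 0))
})

test_that("archetype selection matches a sort oracle and allows overlap", {
  set.seed(13)
  trio <- lineage_marker_panel()$trio
  genes <- unique(unlist(trio))
  v <- matrix(runif(60 * length(genes), 0, 8), 60, length(genes),
              dimnames = list(sprintf("c%02d", 1:60), genes))
  arch <- select_archetype_cells(log_expr(v), top_n = 50)
  mu <- rowMeans(v[, trio$ADC])
  oracle <- names(sort(mu[mu > 0], decreasing = TRUE))[1:50]
  expect_setequal(arch$ADC, oracle)

  top1 <- select_archetype_cells(log_expr(v), top_n = 1)
  expect_identical(top1$SCC, names(which.max(rowMeans(v[, trio$SCC]))))

  # one cell dominating two trios appears in both lists
  v2 <- v; v2["c01", ] <- 9
  a2 <- suppressWarnings(select_archetype_cells(log_expr(v2), top_n = 5))
  expect_true("c01" %in% a2$ADC && "c01" %in% a2$SCC)
})

test_that("signature discovery recovers planted lineage programs", {
  sim <- small_sim()
  ev <- epithelial_view(sim)
  tumor <- ev$truth$tissue == "tumor"
  m_tum <- ev$m[which(tumor), seq_len(ncol(ev$m))]
  arch <- select_archetype_cells(m_tum, top_n = 50)
  sig <- suppressWarnings(lineage_signatures(ev$m, arch, de_params(), 50))
  planted <- function(l) c(lineage_marker_panel()$full[[l]],
                           c(ADC = "CEACAM6", SCC = "TRIM29", NET = "TUBB3")[[l]],
                           sprintf("%s_PROG%03d", l, 1:59))
  expect_gte(sum(sig$ADC %in% planted("ADC")), 45)
  expect_gte(sum(sig$SCC %in% planted("SCC")), 45)
  expect_gte(sum(sig$NET %in% planted("NET")), 45)
  # one-vs-rest positive signatures are pairwise disjoint
  expect_length(intersect(sig$ADC, sig$SCC), 0)
  expect_length(intersect(sig$ADC, sig$NET), 0)
  expect_length(intersect(sig$SCC, sig$NET), 0)
})

test_that("ternary scores scale to [0,100] with normalized compositions", {
  sig <- structure(list(ADC = c("a1", "a2"), SCC = c("s1", "s2"),
                        NET = c("n1", "n2")), class = "lineage_signatures")
  v <- rbind(zero = c(0, 0, 0, 0, 0, 0),
             amax = c(5, 5, 1, 0, 1, 0),
             eq   = c(2, 2, 2, 2, 2, 2))
  colnames(v) <- c("a1", "a2", "s1", "s2", "n1", "n2")
  ts <- ternary_scores(log_expr(v), sig)
  z <- ts[ts$cell_id == "zero", ]
  expect_equal(unlist(z[, c("A", "S", "N")]), c(A = 0, S = 0, N = 0),
               ignore_attr = TRUE)
  expect_true(is.na(z$comp_a))
  expect_equal(ts$A[ts$cell_id == "amax"], 100)
  eqr <- ts[ts$cell_id == "eq", ]
  expect_equal(unlist(eqr[, c("comp_a", "comp_s", "comp_n")]),
               rep(1 / 3, 3), ignore_attr = TRUE)
})

test_that("external matrices are scored after dropping marker-negative cells", {
  set.seed(14)
  genes <- unique(unlist(lineage_marker_panel()$trio))
  n_pos <- 200
  v <- matrix(0, n_pos + 50, length(genes),
              dimnames = list(sprintf("c%03d", 1:(n_pos + 50)), genes))
  mixed_n <- round(0.12 * n_pos)
  for (i in 1:n_pos) {
    if (i <= mixed_n) {
      v[i, c("NKX2-1", "KRT7", "NAPSA")] <- runif(3, 6.5, 8)
      v[i, c("TP63", "KRT5", "KRT6A")] <- runif(3, 6.5, 8)
    } else {
      v[i, c("NKX2-1", "KRT7", "NAPSA")] <- runif(3, 6.5, 8)
    }
  }
  # 50 cells with no marker above the floor must leave the denominator
  res <- apply_to_external(log_expr(v), which_panel = "trio")
  expect_equal(res$n_dropped, 50)
  expect_equal(res$n_scored, n_pos)
  expect_equal(res$mixed_fraction, 0.12, tolerance = 0.25)

  # consistency: identical input gives identical labels
  res2 <- apply_to_external(log_expr(v), which_panel = "trio")
  expect_identical(res$subtype, res2$subtype)
})
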