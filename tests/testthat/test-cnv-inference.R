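five_gene_ann <- function(chrom = "chr1") {
  gene_annotation(data.frame(gene_id = paste0("g", 1:5), chromosome = chrom,
                             start = seq(0, 4e6, 1e6),
                             end = seq(0, 4e6, 1e6) + 1000))
}

test_that("gene moving average matches hand computation and edge rules", {
  v <- matrix(c(0, 0, 3, 0, 0), 1, 5,
              dimnames = list("c1", paste0("g", 1:5)))
  sm <- gene_moving_average(log_expr(v), five_gene_ann(), k = 3)
  expect_equal(unname(sm$smoothed[1, ]), c(0, 1, 1, 1, 0))

  # k = 1 is the identity; a constant matrix stays constant
  sm1 <- gene_moving_average(log_expr(v), five_gene_ann(), k = 1)
  expect_equal(sm1$smoothed, expr_values(log_expr(v)))
  cv <- matrix(2.5, 3, 5, dimnames = list(paste0("c", 1:3), paste0("g", 1:5)))
  smc <- gene_moving_average(log_expr(cv), five_gene_ann(), k = 4)
  expect_true(all(smc$smoothed == 2.5))
})

test_that("moving average and window means equal brute-force oracles", {
  set.seed(20)
  n_genes <- 50
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:n_genes),
    chromosome = rep(c("chr1", "chr2"), each = 25),
    start = rep(seq(0, 48e6, 2e6), 2), end = rep(seq(0, 48e6, 2e6), 2) + 1e4))
  v <- matrix(runif(8 * n_genes, 0, 10), 8, n_genes,
              dimnames = list(sprintf("c%d", 1:8), ann$gene_id))
  k <- 7
  sm <- gene_moving_average(log_expr(v), ann, k = k)
  # oracle: explicit window mean per chromosome with truncation
  for (ch in c("chr1", "chr2")) {
    ids <- ann$gene_id[ann$chromosome == ch]
    for (j in seq_along(ids)) {
      lo <- max(1, j - floor(k / 2)); hi <- min(length(ids), j + k - floor(k / 2) - 1)
      expect_equal(sm$smoothed[, ids[j]],
                   rowMeans(v[, ids[lo:hi], drop = FALSE]))
    }
  }
  centered <- center_by_normals(sm$smoothed, c("c1", "c2"))
  prof <- window_scores(centered, sm$annotation, window_bp = 1e7)
  # oracle: mean of centered gene scores per half-open 10-Mb window
  for (w in seq_len(nrow(prof$windows))) {
    win <- prof$windows[w, ]
    ids <- ann$gene_id[ann$chromosome == win$chromosome &
                         ann$start >= win$start & ann$start < win$end]
    expect_equal(unname(prof$scores[, w]),
                 unname(rowMeans(centered[, ids, drop = FALSE])))
  }
})

test_that("centering zeroes the normal reference and clips extremes", {
  set.seed(21)
  sm <- matrix(rnorm(6 * 10), 6, 10,
               dimnames = list(sprintf("c%d", 1:6), sprintf("g%02d", 1:10)))
  cen <- center_by_normals(sm, c("c1", "c2", "c3"), clip = 3)
  expect_equal(unname(colMeans(cen[1:3, ])), rep(0, 10), tolerance = 1e-12)
  expect_true(all(abs(cen) <= 3))
  # identical tumor and normal profiles center to all zeros
  same <- matrix(5, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  expect_true(all(center_by_normals(same, c("c1", "c2")) == 0))
  expect_error(center_by_normals(sm, "nope"), "normal reference")
})

test_that("windows average their genes and drop empties", {
  ann <- gene_annotation(data.frame(gene_id = c("g1", "g2", "g3"),
                                    chromosome = "chr1",
                                    start = c(1e6, 2e6, 55e6),
                                    end = c(1e6, 2e6, 55e6) + 1000))
  cen <- matrix(c(1, -1, 4), 1, 3, dimnames = list("c1", ann$gene_id))
  prof <- window_scores(cen, ann, window_bp = 1e7)
  expect_equal(nrow(prof$windows), 2)   # the empty windows are absent
  expect_equal(unname(prof$scores[1, ]), c(0, 4))
})

test_that("CNV clusters separate planted clones and drop small clusters strictly", {
  set.seed(22)
  base <- matrix(rnorm(60 * 20, 0, 0.05), 60, 20,
                 dimnames = list(sprintf("c%02d", 1:60), sprintf("w%02d", 1:20)))
  base[1:30, 1:5] <- base[1:30, 1:5] + 1   # planted clone
  prof <- structure(list(scores = base,
                         windows = data.frame(chromosome = "chr1",
                                              start = (0:19) * 1e7,
                                              end = (1:20) * 1e7,
                                              n_genes = 1)),
                    class = "cnv_profile")
  lab <- cluster_cnv(prof, n_cnv_clusters = 2, min_cluster_cells = 10)
  expect_equal(ari(lab, rep(1:2, each = 30)), 1)
  expect_false(any(lab == "dropped"))

  # a cluster of exactly 10 cells is dropped under the strict "> 10" rule
  small <- base[1:40, ]
  small[1:10, 6:10] <- small[1:10, 6:10] + 2
  prof2 <- structure(list(scores = small, windows = prof$windows),
                     class = "cnv_profile")
  lab2 <- cluster_cnv(prof2, n_cnv_clusters = 2, min_cluster_cells = 10)
  expect_identical(unname(lab2[1]), "dropped")
  expect_equal(sum(lab2 == "dropped"), 10)
})

test_that("planted expression CNVs give positive centered scores in the segment", {
  cfg <- simulation_config(
    n_patients = 1, cells_per_patient = 250,
    stromal_fraction = c(fibroblast = 0.01, B = 0.01, T = 0.02,
                         myeloid = 0.01, mast = 0.005),
    cnv_segments = data.frame(chromosome = "chr4", start = 3e7, end = 8e7,
                              fold_change = 2),
    seed = 23)
  sim <- simulate_single_cell_dataset(cfg)
  ev <- epithelial_view(sim)
  sm <- gene_moving_average(ev$m, sim$genes, k = 100)
  cen <- center_by_normals(sm$smoothed,
                           ev$truth$cell_id[ev$truth$tissue == "normal"])
  prof <- window_scores(cen, sm$annotation)
  tum <- ev$truth$cell_id[ev$truth$tissue == "tumor"]
  wmean <- colMeans(prof$scores[tum, ])
  inseg <- prof$windows$chromosome == "chr4" &
    prof$windows$start >= 3e7 & prof$windows$start < 8e7
  neutral <- prof$windows$chromosome != "chr4"
  expect_gt(mean(wmean[inseg]), mean(wmean[neutral]) + 2 * sd(wmean[neutral]))
})

test_that("WGS window profiles normalize per sample and flag concordance", {
  # uniform reads: equal depth per equal-length window
  rt <- data.frame(chromosome = "chr1",
                   position = rep(seq(5e5, 9.95e7, 1e6), 2),
                   sample = rep(c("tumor", "normal"), each = 100))
  wp <- wgs_window_profile(rt)
  expect_true(all(abs(wp$depth - 0.1) < 1e-12))

  # doubling one sample's reads leaves its normalized profile unchanged
  rt2 <- rbind(rt, rt[rt$sample == "tumor", ])
  wp2 <- wgs_window_profile(rt2)
  expect_equal(wp2$depth[wp2$sample == "tumor"],
               wp$depth[wp$sample == "tumor"])

  prof <- structure(list(scores = matrix(c(1, 1, -1, 0.5), 1, 4,
                                         dimnames = list("c1", NULL)),
                         windows = data.frame(chromosome = "chr1",
                                              start = (0:3) * 1e7,
                                              end = (1:4) * 1e7,
                                              n_genes = 1)),
                    class = "cnv_profile")
  wgs <- data.frame(sample = rep(c("tumor", "normal"), each = 4),
                    chromosome = "chr1", start = rep((0:3) * 1e7, 2),
                    end = rep((1:4) * 1e7, 2),
                    n_reads = c(20, 20, 5, 15, 10, 10, 10, 10),
                    depth = c(20, 20, 5, 15, 10, 10, 10, 10) / 60)
  cc <- concordance(prof, wgs)
  expect_equal(cc$agreement, 1)
  # inverting the scRNA signs drives agreement to zero
  prof$scores <- -prof$scores
  expect_equal(concordance(prof, wgs)$agreement, 0)
  # a neutral genome leaves agreement undefined
  wgs$depth <- rep(0.125, 8)
  expect_message(cc3 <- concordance(prof, wgs), "undefined")
  expect_true(is.na(cc3$agreement))
})
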