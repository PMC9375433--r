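test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(n_patients = 1, cells_per_patient = 40, seed = 9)
  a <- simulate_single_cell_dataset(cfg)
  b <- simulate_single_cell_dataset(cfg)
  expect_identical(expr_values(a$expression), expr_values(b$expression))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$mito_afm, b$mito_afm)
  expect_identical(simulate_bulk_cohort(cfg), simulate_bulk_cohort(cfg))
  expect_identical(simulate_wgs_read_table(cfg), simulate_wgs_read_table(cfg))
})

test_that("lineage weights respect the planted mixing structure", {
  pure <- simulate_single_cell_dataset(
    simulation_config(n_patients = 1, cells_per_patient = 60,
                      mixed_lineage_fraction = 0, seed = 2))
  w <- pure$truth$cells[, c("w_ADC", "w_SCC", "w_NET")]
  tumor_epi <- !is.na(w$w_ADC)
  expect_true(all(rowSums(w[tumor_epi, ] > 0) == 1))

  mixed <- simulate_single_cell_dataset(
    simulation_config(n_patients = 1, cells_per_patient = 80,
                      mixed_lineage_fraction = 1, seed = 3))
  wm <- mixed$truth$cells[, c("w_ADC", "w_SCC", "w_NET")]
  te <- !is.na(wm$w_ADC)
  expect_true(all(abs(rowSums(wm[te, ]) - 1) < 1e-12))
  expect_true(all(rowSums(wm[te, ] > 0) >= 2))
  # every active weight stays above the detectability floor
  expect_true(all(wm[te, ][wm[te, ] > 0] >= 0.2))
})

test_that("planted CNV segments double mean expression of covered genes", {
  cfg <- simulation_config(
    n_patients = 2, cells_per_patient = 300,
    stromal_fraction = c(fibroblast = 0.01, B = 0.01, T = 0.02,
                         myeloid = 0.01, mast = 0.005),
    cnv_segments = data.frame(chromosome = "chr5", start = 0, end = 5e7,
                              fold_change = 2),
    seed = 5)
  sim <- simulate_single_cell_dataset(cfg)
  tr <- sim$truth$cells
  tumor <- tr$cell_id[tr$tissue == "tumor" & tr$true_major_type == "epithelial"]
  normal <- tr$cell_id[tr$tissue == "normal" & tr$true_major_type == "epithelial"]
  expect_gt(length(tumor), 250)
  ann <- sim$genes
  inseg <- ann$gene_id[ann$chromosome == "chr5" & ann$start < 5e7 &
                         startsWith(ann$gene_id, "BG")]
  v <- expr_values(sim$expression)
  ratio <- mean(v[tumor, inseg]) / mean(v[normal, inseg])
  expect_equal(ratio, 2, tolerance = 0.1)
  # normal epithelial cells carry no tumor mito clone
  expect_false(any(tr$mito_clone[tr$tissue == "normal"]))
})

test_that("bulk cohorts follow the proportional-hazards construction", {
  cfg0 <- simulation_config(survival = list(n_samples = 60,
                                            baseline_hazard = 0.02,
                                            hazard_ratio = 2,
                                            censoring_rate = 0),
                            seed = 11)
  coh <- simulate_bulk_cohort(cfg0)
  expect_true(all(coh$event == 1))
  expect_true(all(abs(rowSums(coh[, c("A", "S", "N")]) - 1) < 1e-9))
  expect_equal(coh$score,
               (1 - pmax(coh$A, coh$S, coh$N)) / pmax(coh$A, coh$S, coh$N))

  bad <- simulation_config(survival = list(n_samples = 60,
                                           baseline_hazard = 0.02,
                                           hazard_ratio = -1,
                                           censoring_rate = 0), seed = 1)
  expect_error(simulate_bulk_cohort(bad), "hazard ratio")

  # strong mixing effect: high-score group dies earlier
  cfg_hr <- simulation_config(survival = list(n_samples = 300,
                                              baseline_hazard = 0.02,
                                              hazard_ratio = 10,
                                              censoring_rate = 0.1),
                              seed = 12)
  ch <- simulate_bulk_cohort(cfg_hr)
  hi <- ch$score > stats::median(ch$score)
  med_hi <- km_median(kaplan_meier(ch$time[hi], ch$event[hi]))
  med_lo <- km_median(kaplan_meier(ch$time[!hi], ch$event[!hi]))
  expect_lt(med_hi, med_lo)
})

test_that("WGS read tables reflect window copy states and depth normalization", {
  flat <- simulation_config(cnv_segments = data.frame(chromosome = character(),
                                                      start = numeric(),
                                                      end = numeric(),
                                                      fold_change = numeric()),
                            wgs_depth = 2e5, seed = 7)
  rt <- simulate_wgs_read_table(flat)
  wp <- wgs_window_profile(rt)
  t_depth <- wp$depth[wp$sample == "tumor"]
  n_depth <- wp$depth[wp$sample == "normal"]
  expect_equal(length(t_depth), 50)
  expect_equal(t_depth / n_depth, rep(1, 50), tolerance = 0.15)

  amp <- simulation_config(cnv_segments = data.frame(chromosome = "chr2",
                                                     start = 0, end = 4e7,
                                                     fold_change = 2),
                           wgs_depth = 4e5, seed = 8)
  wp2 <- wgs_window_profile(simulate_wgs_read_table(amp))
  tum <- wp2[wp2$sample == "tumor", ]
  nor <- wp2[wp2$sample == "normal", ]
  covered <- tum$chromosome == "chr2" & tum$start < 4e7
  ratio <- tum$depth[covered] / nor$depth[covered]
  expect_equal(mean(ratio), 2, tolerance = 0.1)

  # doubling depth leaves the normalized profile unchanged in expectation
  deep <- simulation_config(cnv_segments = amp$cnv_segments,
                            wgs_depth = 8e5, seed = 8)
  wp3 <- wgs_window_profile(simulate_wgs_read_table(deep))
  expect_equal(wp3$depth[wp3$sample == "tumor"],
               wp2$depth[wp2$sample == "tumor"], tolerance = 0.1)
})
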