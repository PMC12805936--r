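test_that("mitochondrial percentage and detected-gene counts are exact", {
  m <- matrix(c(30, 100, 0,
                70, 0, 0), nrow = 2, byrow = TRUE)
  x <- make_counts(m, genes = c("MT-CO1", "ACTB"))
  qc <- compute_cell_qc(x)
  expect_equal(qc$mito_pct, c(30, 100, 0))
  expect_equal(qc$n_genes, c(2, 1, 0))
  expect_true(qc$zero_total[3])
  # per cell, mito percent recovers the mito/total count split exactly
  expect_equal(qc$mito_pct / 100 * qc$total_counts, c(30, 100, 0))
})

test_that("cells sitting exactly on both 50% boundaries are kept", {
  m <- matrix(c(50, 50), nrow = 2)  # one cell, mito_pct exactly 50
  x <- make_counts(m, genes = c("MT-ND1", "ACTB"))
  qc <- compute_cell_qc(x, align_stats = data.frame(cell_id = "c1",
                                                    unique_map_pct = 50.0))
  flt <- filter_cells(qc)
  expect_identical(flt$kept, "c1")
  expect_equal(nrow(flt$removed), 0)
})

test_that("removed cells carry every applicable reason", {
  m <- matrix(c(60, 10,
                40, 90), nrow = 2, byrow = TRUE)  # c1: 60% mito; c2: 10%
  x <- make_counts(m, genes = c("MT-ND1", "ACTB"))
  stats <- data.frame(cell_id = c("c1", "c2"), unique_map_pct = c(30, 80))
  flt <- filter_cells(compute_cell_qc(x, stats))
  expect_identical(flt$kept, "c2")
  expect_setequal(flt$removed$reasons[[1]],
                  c("low_unique_mapping", "high_mitochondrial"))
})

test_that("a 41-cell cohort with 3 mapping and 1 mito failure keeps 37", {
  sim <- simulate_ctc_counts(sim_config(n_genes = 500, seed = 11))
  ctc <- sim$truth$cell_table$cell_id[sim$truth$cell_table$group == "CTC"]
  expect_length(ctc, 41)
  qc <- compute_cell_qc(subset_counts(sim$counts, cells = ctc),
                        sim$align_stats)
  flt <- filter_cells(qc)
  expect_length(flt$kept, 37)
  reason1 <- vapply(flt$removed$reasons, `[[`, "", 1)
  expect_equal(sum(reason1 == "low_unique_mapping"), 3)
  expect_equal(sum(reason1 == "high_mitochondrial"), 1)
  planted <- sim$truth$cell_table
  expect_setequal(flt$removed$cell_id,
                  planted$cell_id[planted$planted_fail != "none"])
})

test_that("cell filtering is idempotent and partitions the input", {
  sim <- simulate_ctc_counts(sim_config(n_genes = 300, seed = 2))
  qc <- compute_cell_qc(sim$counts, sim$align_stats)
  flt <- filter_cells(qc)
  expect_setequal(c(flt$kept, flt$removed$cell_id), qc$cell_id)
  expect_length(intersect(flt$kept, flt$removed$cell_id), 0)
  qc2 <- qc[qc$cell_id %in% flt$kept, ]
  flt2 <- filter_cells(qc2)
  expect_identical(flt2$kept, flt$kept)
  # raising the mito ceiling never removes additional cells
  relaxed <- filter_cells(qc, qc_thresholds(max_mito_pct = 80))
  expect_true(all(flt$kept %in% relaxed$kept))
})

test_that("gene filter uses an at-least-min_cells rule and is idempotent", {
  m <- rbind(g_in4 = c(1, 1, 1, 1, 0, 0),
             g_in5 = c(1, 1, 1, 1, 1, 0),
             g_all = 1)
  x <- count_matrix(m, rownames(m), sprintf("c%d", 1:6))
  f <- filter_genes(x, min_cells = 5)
  expect_setequal(f$gene_ids, c("g_in5", "g_all"))
  expect_identical(filter_genes(f, 5)$gene_ids, f$gene_ids)
  expect_identical(filter_genes(x, 0)$gene_ids, x$gene_ids)
  expect_identical(f$cell_ids, x$cell_ids)
})

test_that("detection summary reports median, range and mean", {
  m <- cbind(c(1, 1, 1, rep(0, 27)), c(rep(1, 20), rep(0, 10)), rep(1, 30))
  x <- make_counts(m)
  s <- detection_summary(x)
  expect_equal(s$median, 20)
  expect_equal(c(s$min, s$max), c(3, 30))
  expect_equal(s$mean, mean(c(3, 20, 30)))
  one <- detection_summary(x, cells = "c2")
  expect_equal(one$median, one$min)
  expect_equal(one$median, one$max)
  expect_error(detection_summary(x, cells = character(0)), "empty")
})

test_that("feature floor is a flag by default and a filter in strict mode", {
  m <- rbind(rep(1, 2), c(1, 0))
  x <- make_counts(m)
  qc <- compute_cell_qc(x)
  default <- filter_cells(qc, qc_thresholds(min_features_per_cell = 2))
  expect_length(default$kept, 2)
  strict <- filter_cells(qc, qc_thresholds(min_features_per_cell = 2,
                                           enforce_min_features = TRUE))
  expect_identical(strict$kept, "c1")
  expect_identical(strict$removed$reasons[[1]], "low_feature_count")
})
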