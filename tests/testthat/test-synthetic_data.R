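test_that("every generator is deterministic in its seed", {
  cfg <- sim_config(n_genes = 300, seed = 99)
  a <- simulate_ctc_counts(cfg); b <- simulate_ctc_counts(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a$counts$counts,
    simulate_ctc_counts(sim_config(n_genes = 300, seed = 100))$counts$counts))
  expect_identical(simulate_references(cfg, a$truth),
                   simulate_references(cfg, a$truth))
  expect_identical(simulate_if_image(5, 5, 0.5, seed = 3),
                   simulate_if_image(5, 5, 0.5, seed = 3))
  expect_identical(simulate_flow_events(10, 10, 0.5, seed = 3),
                   simulate_flow_events(10, 10, 0.5, seed = 3))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_ctc_counts(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("emitted references never contradict the gene-class truth", {
  b <- simulate_full_study(sim_config(n_genes = 800, seed = 21))
  gt <- b$truth$gene_table
  look <- blood_lookup(b$blood_ref, gt$gene_id)
  ann <- annotation_lookup(b$annotation, gt$gene_id)
  is_membrane <- vapply(ann$locations, function(l) "plasma_membrane" %in% l,
                        logical(1))
  tm <- gt$class == "true_marker"
  expect_true(all(look$pbmc_max_count[tm] == 0))
  expect_true(all(look$blood_expression[tm] <= 15))
  expect_true(all(ann$biotype[tm] == "protein_coding"))
  expect_true(all(is_membrane[tm]))
  expect_true(all(look$pbmc_max_count[gt$class == "decoy_pbmc"] > 0))
  expect_true(all(look$blood_expression[gt$class == "decoy_blood"] > 15))
  expect_true(all(ann$biotype[gt$class == "decoy_biotype"] != "protein_coding"))
  expect_true(!any(is_membrane[gt$class == "decoy_location"]))
  # each background gene carries at least one disqualifying property
  bg <- gt$class == "background"
  disqualified <- look$pbmc_max_count > 0 | look$blood_expression > 15 |
    ann$biotype != "protein_coding" | !is_membrane
  expect_true(all(disqualified[bg]))
})

test_that("planted detection fractions are realized exactly", {
  cfg <- sim_config(n_genes = 300, seed = 31,
                    marker_detect_frac = c(AHNAK2 = 1, CAVIN1 = 1, ODR4 = 1,
                                           TRIML2 = 1, S100A16 = 1, EGFR = 1))
  sim <- simulate_ctc_counts(cfg)
  gt <- sim$truth$gene_table
  expect_true(all(gt$detect_frac_ctc[gt$class == "true_marker"] == 1))
  frac <- sim_config(n_genes = 300, seed = 31)$marker_detect_frac
  sim2 <- simulate_ctc_counts(sim_config(n_genes = 300, seed = 31))
  gt2 <- sim2$truth$gene_table
  for (g in names(frac)) {
    expect_equal(gt2$detect_frac_ctc[gt2$gene_id == g],
                 round(frac[[g]] * 37) / 37)
  }
  expect_equal(gt2$detect_frac_ctc[gt2$gene_id == "DECOY_UNEXPR"], 0)
})

test_that("decoy expression contracts hold: dim HER2, sparse EPCAM", {
  b <- simulate_full_study(sim_config(n_genes = 1000, seed = 41))
  kept <- b$truth$kept_ctc
  norm <- normalize_log2(subset_counts(b$counts, cells = kept))
  me <- mean_normalized_expression(norm)
  expect_lt(me[["HER2"]], 8)          # fails only the expression filter
  expect_gte(me[["EPCAM"]], 8)        # passes expression ...
  expect_lt(detection_fraction(b$counts, "EPCAM", kept)$fraction, 0.30)
  expect_gte(detection_fraction(b$counts, "HER2", kept)$fraction, 0.30)
  expect_gte(me[["ATP23"]], 8)        # curation decoy clears everything else
  expect_gte(detection_fraction(b$counts, "ATP23", kept)$fraction, 0.30)
})

test_that("image generator plants exact classes and marker fractions", {
  sim <- simulate_if_image(n_ctc = 20, n_immune = 80,
                           frac_marker_positive = 0.9, seed = 12)
  expect_equal(nrow(sim$truth), 100)
  expect_equal(sum(sim$truth$class == "ctc"), 20)
  expect_equal(sum(sim$truth$marker_positive), 18)
  expect_equal(sim$realized_fraction, 0.9)
  expect_true(all(!sim$truth$marker_positive[sim$truth$class == "immune"]))
  labels <- segment_nuclei(sim$stack, segmentation_config(min_area = 10))
  expect_equal(max(labels), 100)
})

test_that("flow generator plants exact gate membership and positivity", {
  sim <- simulate_flow_events(n_gated = 500, n_outside = 1500,
                              frac_marker_positive = 0.4, seed = 22)
  expect_equal(sum(sim$truth$gated), 500)
  expect_equal(sum(sim$truth$marker_positive), 200)
  g <- gate_events(sim$events, gate_config(0.4, 0.4, 0.4))
  expect_equal(g$fraction, 0.4)
  expect_equal(g$n_gated, 500)
})

test_that("configs are validated", {
  expect_error(sim_config(n_genes = 20), "n_genes")
  expect_error(sim_config(marker_detect_frac = c(AHNAK2 = 2, CAVIN1 = 1,
                                                 ODR4 = 1, TRIML2 = 1,
                                                 S100A16 = 1, EGFR = 1)))
  expect_error(simulate_if_image(0, 0, 0.5))
})
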