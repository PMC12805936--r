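test_that("subtraction filters honor strict-inequality boundaries", {
  ref <- blood_reference(c("a", "b", "c", "d"),
                         pbmc_max_count = c(0, 1e-4, 0, 0),
                         blood_expression = c(15, 0, 15.01, 3))
  genes <- c("a", "b", "c", "d", "absent")
  expect_setequal(subtract_pbmc_expressed(genes, ref),
                  c("a", "c", "d", "absent"))   # any PBMC count > 0 removed
  expect_setequal(subtract_whole_blood(genes, ref),
                  c("a", "b", "d", "absent"))   # exactly 15 kept, 15.01 out
})

test_that("expression filter keeps the boundary and handles percentile ties", {
  me <- c(a = 7.999, b = 8, c = 20)
  expect_setequal(filter_by_expression(names(me), me), c("b", "c"))

  me100 <- setNames(seq_len(100), sprintf("g%03d", 1:100))
  top <- filter_by_expression(names(me100), me100,
                              cascade_config(expression_mode = "percentile"))
  expect_setequal(top, sprintf("g%03d", 96:100))

  tied <- setNames(c(rep(1, 90), rep(5, 10)), sprintf("t%03d", 1:100))
  kept <- filter_by_expression(names(tied), tied,
                               cascade_config(expression_mode = "percentile"))
  expect_setequal(kept, sprintf("t%03d", 91:100))  # all ties retained

  expect_error(filter_by_expression(c("a", "zz"), me), "missing")
})

test_that("coverage filter applies the 30%-of-CTCs rule inclusively", {
  cells <- sprintf("c%02d", 1:37)
  m <- rbind(in11 = c(rep(1, 11), rep(0, 26)),
             in12 = c(rep(1, 12), rep(0, 25)),
             everywhere = rep(3, 37))
  x <- count_matrix(m, rownames(m), cells)
  kept <- filter_by_coverage(rownames(m), x)
  expect_setequal(kept, c("in12", "everywhere"))  # 11/37 < 0.30 <= 12/37
  ten <- rbind(in3 = c(1, 1, 1, rep(0, 7)))
  x10 <- count_matrix(ten, "in3", sprintf("d%d", 1:10))
  expect_identical(filter_by_coverage("in3", x10), "in3")  # exactly 30% kept
})

test_that("biotype and location filters remove unknowns conservatively", {
  ann <- gene_annotation(c("pc_pm", "pc_cyt", "linc_pm", "pc_none"),
                         biotype = c("protein_coding", "protein_coding",
                                     "lincRNA", "protein_coding"),
                         locations = list(c("plasma_membrane", "cytosol"),
                                          "cytosol", "plasma_membrane",
                                          character(0)))
  genes <- c("pc_pm", "pc_cyt", "linc_pm", "pc_none", "unannotated")
  coding <- filter_protein_coding(genes, ann)
  expect_setequal(as.character(coding), c("pc_pm", "pc_cyt", "pc_none"))
  expect_identical(attr(coding, "unannotated"), "unannotated")
  membrane <- filter_plasma_membrane(genes, ann)
  expect_setequal(as.character(membrane), c("pc_pm", "linc_pm"))
})

test_that("curation intersects, warns on unknown genes, appends whitelist", {
  survivors <- c("A", "B", "C")
  cand <- apply_curation(survivors, keep_list = c("A", "C"))
  expect_identical(cand$gene, c("A", "C"))
  expect_false(any(cand$known))
  expect_warning(apply_curation(survivors, c("A", "NOPE")), "NOPE")
  wl <- apply_curation(survivors, keep_list = "A", whitelist = "EGFR")
  expect_identical(wl$gene, c("A", "EGFR"))
  expect_identical(wl$known, c(FALSE, TRUE))
  empty <- apply_curation(survivors, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("the cascade recovers exactly the planted markers", {
  b <- simulate_full_study(sim_config(n_genes = 2000, seed = 17))
  kept <- b$truth$kept_ctc
  counts <- filter_genes(subset_counts(
    b$counts, cells = c(kept, b$align_stats$cell_id[
      startsWith(b$align_stats$cell_id, "LM2")])), 5)
  res <- run_cascade(counts, b$blood_ref, b$annotation, cells = kept,
                     curation = b$curation, whitelist = b$whitelist)
  truth_markers <- b$truth$gene_table$gene_id[
    b$truth$gene_table$class == "true_marker"]
  expect_setequal(res$candidates$gene, truth_markers)
  # the stage before curation holds the markers plus the curation decoy only
  pre <- res$stages[[which(vapply(res$stages, `[[`, "", "name") ==
                             "plasma_membrane")]]$genes
  expect_setequal(pre, c(truth_markers, "ATP23"))
})

test_that("stage outputs are nested and counts weakly decreasing", {
  b <- simulate_full_study(sim_config(n_genes = 300, seed = 23))
  res <- run_cascade(b$counts, b$blood_ref, b$annotation,
                     cells = b$truth$kept_ctc, curation = b$curation)
  sets <- lapply(res$stages, `[[`, "genes")
  for (k in seq_along(sets)[-1]) {
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
  counts <- cascade_counts(res)
  expect_true(all(diff(counts$n_out) <= 0))
  expect_equal(counts$n_in[-1], counts$n_out[-nrow(counts)])
})

test_that("tightening one threshold never grows a downstream stage", {
  b <- simulate_full_study(sim_config(n_genes = 400, seed = 31))
  loose <- run_cascade(b$counts, b$blood_ref, b$annotation,
                       cells = b$truth$kept_ctc,
                       cfg = cascade_config(blood_expr_max = 15))
  tight <- run_cascade(b$counts, b$blood_ref, b$annotation,
                       cells = b$truth$kept_ctc,
                       cfg = cascade_config(blood_expr_max = 5))
  expect_true(all(cascade_counts(tight)$n_out <= cascade_counts(loose)$n_out))
})

test_that("a fully permissive configuration reduces to the expressed set", {
  b <- simulate_full_study(sim_config(n_genes = 300, seed = 41))
  ann_all <- gene_annotation(b$counts$gene_ids, b$counts$gene_ids,
                             rep("protein_coding", length(b$counts$gene_ids)),
                             rep(list("plasma_membrane"),
                                 length(b$counts$gene_ids)))
  ref_none <- blood_reference(character(0), numeric(0), numeric(0))
  cfg <- cascade_config(pbmc_count_max = Inf, blood_expr_max = Inf,
                        min_mean_expr = 0, min_detect_frac = 0)
  expressed <- drop_unexpressed(b$counts, b$truth$kept_ctc)
  res <- run_cascade(b$counts, ref_none, ann_all, cfg,
                     cells = b$truth$kept_ctc, curation = expressed)
  expect_setequal(res$candidates$gene, expressed)
})

test_that("cascade errors carry the failing stage's name", {
  b <- simulate_full_study(sim_config(n_genes = 300, seed = 43))
  expect_error(run_cascade(b$counts, b$blood_ref, NULL,
                           cells = b$truth$kept_ctc),
               "protein_coding")
})
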