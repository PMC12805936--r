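#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study bundle and write it to disk in the
# pipeline's exchange formats (Matrix Market counts + label files, TSV
# reference tables). Later steps read these files back through the package
# readers, so the full I/O surface is exercised.

suppressPackageStartupMessages(library(ctcscreen))

seed <- 1L
out <- "results/sim_study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bundle <- simulate_full_study(sim_config(seed = seed))

write_count_matrix(bundle$counts,
                   file.path(out, "counts.mtx"),
                   file.path(out, "genes.txt"),
                   file.path(out, "cells.txt"))
write.table(data.frame(cell_id = names(bundle$counts$cell_groups),
                       group = unname(bundle$counts$cell_groups)),
            file.path(out, "cell_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bundle$align_stats, file.path(out, "align_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bundle$blood_ref[, c("gene_id", "pbmc_max_count")],
            file.path(out, "pbmc_reference.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bundle$blood_ref[, c("gene_id", "blood_expression")],
            file.path(out, "blood_reference.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ann <- bundle$annotation
write.table(data.frame(gene_id = ann$gene_id, symbol = ann$symbol,
                       biotype = ann$biotype,
                       locations = vapply(ann$locations, paste, "",
                                          collapse = ";")),
            file.path(out, "gene_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(bundle$curation, file.path(out, "curation_keep_list.txt"))
writeLines(bundle$whitelist, file.path(out, "known_marker_whitelist.txt"))
write.table(bundle$truth$gene_table, file.path(out, "truth_gene_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bundle$truth$cell_table, file.path(out, "truth_cell_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d cells (seed %d)\n",
            length(bundle$counts$gene_ids), length(bundle$counts$cell_ids),
            seed))
cat(sprintf("planted: %d true markers, %d decoys, %d QC-failing cells\n",
            sum(bundle$truth$gene_table$class == "true_marker"),
            sum(startsWith(bundle$truth$gene_table$class, "decoy")),
            sum(bundle$truth$cell_table$planted_fail != "none")))
cat("bundle written to", out, "\n")
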