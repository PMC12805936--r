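#!/usr/bin/env Rscript
# Step 4 — detection statistics for the published, new and total marker
# cocktails over the QC-passing CTCs: per-marker detection fractions and the
# number of CTCs missed by each cocktail as a whole.

suppressPackageStartupMessages(library(ctcscreen))

src <- "results/sim_study"
out <- "results"

groups_df <- read.table(file.path(src, "cell_groups.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
counts <- read_count_matrix(file.path(src, "counts.mtx"),
                            file.path(src, "genes.txt"),
                            file.path(src, "cells.txt"))
ctc <- intersect(readLines(file.path(out, "kept_cells.txt")),
                 groups_df$cell_id[groups_df$group == "CTC"])

panels <- default_panels()
rows <- list()
for (nm in names(panels)) {
  cov <- panel_coverage(counts, panels[[nm]], ctc)
  cat("--", nm, "cocktail --\n")
  print(cov)
  rows[[nm]] <- data.frame(panel = nm, cov$markers,
                           panel_missed = cov$n_missed)
}
write.csv(do.call(rbind, rows), file.path(out, "panel_coverage.csv"),
          row.names = FALSE)

candidates <- read.csv(file.path(out, "candidates.csv"),
                       stringsAsFactors = FALSE)
cs <- candidate_summary(counts, candidates$gene, ctc)
cat(sprintf("minimum candidate detection: %.1f%% of CTCs\n",
            100 * cs$min_fraction))
write.csv(cs$table, file.path(out, "candidate_detection.csv"),
          row.names = FALSE)
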