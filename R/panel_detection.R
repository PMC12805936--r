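#' Detection fraction of one gene over a cell subset
#'
#' Detection is defined on raw counts (count >= `min_count`), so it is
#' invariant under size-factor normalization.
#'
#' @param counts A `ctc_counts` object.
#' @param gene A gene id present in the matrix.
#' @param cells Cell subset (default all).
#' @param min_count Raw count defining detection; default 1.
#' @return List with `gene`, `n_detected`, `n_cells`, `fraction`.
#' @export
detection_fraction <- function(counts, gene, cells = NULL, min_count = 1) {
  stopifnot(inherits(counts, "ctc_counts"), length(gene) == 1)
  if (!gene %in% counts$gene_ids) stop("unknown gene: ", gene)
  if (is.null(cells)) cells <- counts$cell_ids
  k <- subset_counts(counts, genes = gene, cells = cells)$counts[1, ]
  n_det <- sum(k >= min_count)
  list(gene = gene, n_detected = n_det, n_cells = length(cells),
       fraction = n_det / length(cells))
}

#' Coverage of a marker panel over a cell subset
#'
#' Per-marker detection counts plus the number of cells missed by the whole
#' panel: cells in which no panel member reaches `min_count`.
#'
#' @param counts A `ctc_counts` object.
#' @param panel Non-empty character vector of gene ids.
#' @param cells Cell subset (default all).
#' @param min_count Raw count defining detection; default 1.
#' @return A `panel_stats` list: `markers` (data frame `gene`, `n_detected`,
#'   `n_cells`, `fraction`), `n_missed`, `n_cells`, `missed_cells`.
#' @export
panel_coverage <- function(counts, panel, cells = NULL, min_count = 1) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (!length(panel)) stop("panel_coverage: empty panel")
  missing <- setdiff(panel, counts$gene_ids)
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  if (is.null(cells)) cells <- counts$cell_ids
  m <- subset_counts(counts, genes = panel, cells = cells)$counts
  det <- m >= min_count
  markers <- data.frame(gene = panel,
                        n_detected = rowSums(det),
                        n_cells = length(cells),
                        fraction = rowSums(det) / length(cells),
                        stringsAsFactors = FALSE, row.names = NULL)
  missed <- colSums(det) == 0
  structure(list(markers = markers, n_missed = sum(missed),
                 n_cells = length(cells), missed_cells = cells[missed]),
            class = "panel_stats")
}

#' @export
print.panel_stats <- function(x, ...) {
  cat("panel coverage over", x$n_cells, "cells:\n")
  for (i in seq_len(nrow(x$markers))) {
    cat(sprintf("  %-10s %d of %d (%.1f%%)\n", x$markers$gene[i],
                x$markers$n_detected[i], x$markers$n_cells[i],
                100 * x$markers$fraction[i]))
  }
  cat(sprintf("cells missed by the panel: %d of %d\n", x$n_missed, x$n_cells))
  invisible(x)
}

#' Detection fractions for a candidate list, with the minimum
#'
#' @param counts A `ctc_counts` object.
#' @param candidates Non-empty character vector of gene ids.
#' @param cells Cell subset (default all).
#' @param min_count Raw count defining detection; default 1.
#' @return List with `table` (data frame `gene`, `n_detected`, `n_cells`,
#'   `fraction`) and `min_fraction`.
#' @export
candidate_summary <- function(counts, candidates, cells = NULL, min_count = 1) {
  if (!length(candidates)) stop("candidate_summary: empty candidate list")
  cov <- panel_coverage(counts, candidates, cells, min_count)
  list(table = cov$markers, min_fraction = min(cov$markers$fraction))
}
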