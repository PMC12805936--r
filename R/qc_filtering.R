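#' Quality-control thresholds
#'
#' Defaults follow the strict-inequality wording of the source filters: a cell
#' is removed only if its uniquely-mapped percentage is strictly below 50% or
#' its mitochondrial percentage strictly above 50%; a gene is kept if expressed
#' in at least 5 cells. The per-cell feature floor (1,000 detected genes) is
#' computed and flagged but not enforced unless `enforce_min_features = TRUE`.
#'
#' @param min_unique_map_pct Minimum percent uniquely mapped reads (cells
#'   strictly below are removed). Percent, default 50.
#' @param max_mito_pct Maximum percent mitochondrial reads (cells strictly
#'   above are removed). Percent, default 50.
#' @param min_cells_per_gene Genes expressed in fewer cells are removed.
#'   Default 5.
#' @param min_features_per_cell Detected-gene floor per cell. Default 1000.
#' @param enforce_min_features Apply the feature floor as a removal rule
#'   rather than a flag. Default `FALSE`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_unique_map_pct = 50, max_mito_pct = 50,
                          min_cells_per_gene = 5, min_features_per_cell = 1000,
                          enforce_min_features = FALSE) {
  stopifnot(min_unique_map_pct >= 0, min_unique_map_pct <= 100,
            max_mito_pct >= 0, max_mito_pct <= 100,
            min_cells_per_gene >= 0, min_features_per_cell >= 0)
  structure(list(min_unique_map_pct = min_unique_map_pct,
                 max_mito_pct = max_mito_pct,
                 min_cells_per_gene = min_cells_per_gene,
                 min_features_per_cell = min_features_per_cell,
                 enforce_min_features = isTRUE(enforce_min_features)),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' For each cell: the number of detected genes (raw count > 0), the percentage
#' of total counts attributed to mitochondrial genes, and (when alignment
#' statistics are supplied) the percent uniquely mapped reads. Cells with zero
#' total counts get `mito_pct = 0` and are flagged `zero_total`.
#'
#' @param counts A `ctc_counts` object.
#' @param align_stats Optional data frame with `cell_id`, `unique_map_pct`
#'   (see [read_alignment_stats()]); cells absent from it get `NA`.
#' @param mito_genes Explicit character vector of mitochondrial gene ids; if
#'   `NULL`, genes whose id starts with `mito_prefix` are used.
#' @param mito_prefix Prefix identifying mitochondrial genes (human
#'   convention `"MT-"`).
#' @return Data frame with columns `cell_id`, `n_genes`, `total_counts`,
#'   `mito_pct`, `unique_map_pct`, `zero_total`.
#' @export
compute_cell_qc <- function(counts, align_stats = NULL, mito_genes = NULL,
                            mito_prefix = "MT-") {
  stopifnot(inherits(counts, "ctc_counts"))
  m <- counts$counts
  if (is.null(mito_genes)) {
    mito_genes <- counts$gene_ids[startsWith(counts$gene_ids, mito_prefix)]
  } else {
    missing <- setdiff(mito_genes, counts$gene_ids)
    if (length(missing)) {
      stop("mito_genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  total <- colSums(m)
  mito_total <- if (length(mito_genes)) {
    colSums(m[mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(m))
  }
  mito_pct <- ifelse(total > 0, 100 * mito_total / total, 0)
  qc <- data.frame(cell_id = counts$cell_ids,
                   n_genes = colSums(m > 0),
                   total_counts = total,
                   mito_pct = mito_pct,
                   unique_map_pct = NA_real_,
                   zero_total = total == 0,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(align_stats)) {
    idx <- match(qc$cell_id, align_stats$cell_id)
    qc$unique_map_pct <- align_stats$unique_map_pct[idx]
  }
  qc
}

#' Filter cells on mapping rate and mitochondrial fraction
#'
#' A cell is removed iff `unique_map_pct < min_unique_map_pct` or
#' `mito_pct > max_mito_pct` (strict inequalities: a cell sitting exactly at
#' 50/50 passes both filters). Cells with zero total counts are removed with a
#' dedicated reason. Cells without alignment statistics (`NA`) are not removed
#' by the mapping rule. Each removed cell carries every reason that applies.
#'
#' @param qc Data frame from [compute_cell_qc()].
#' @param thr A `qc_thresholds` object.
#' @return List with `kept` (character vector of cell ids, input order) and
#'   `removed` (data frame `cell_id`, `reasons` list-column).
#' @export
filter_cells <- function(qc, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  reasons <- lapply(seq_len(nrow(qc)), function(i) {
    r <- character(0)
    if (!is.na(qc$unique_map_pct[i]) &&
        qc$unique_map_pct[i] < thr$min_unique_map_pct) {
      r <- c(r, "low_unique_mapping")
    }
    if (qc$mito_pct[i] > thr$max_mito_pct) r <- c(r, "high_mitochondrial")
    if (qc$zero_total[i]) r <- c(r, "zero_total_counts")
    if (thr$enforce_min_features && qc$n_genes[i] < thr$min_features_per_cell) {
      r <- c(r, "low_feature_count")
    }
    r
  })
  drop <- lengths(reasons) > 0
  removed <- data.frame(cell_id = qc$cell_id[drop], stringsAsFactors = FALSE)
  removed$reasons <- reasons[drop]
  list(kept = qc$cell_id[!drop], removed = removed)
}

#' Filter genes by the number of cells expressing them
#'
#' Retains genes with a positive count in at least `min_cells` cells
#' ("expressed by less than `min_cells` cells" removed); the cell set is
#' unchanged.
#'
#' @param counts A `ctc_counts` object.
#' @param min_cells Minimum number of expressing cells; default 5.
#' @return A `ctc_counts` object with the surviving genes.
#' @export
filter_genes <- function(counts, min_cells = 5) {
  stopifnot(inherits(counts, "ctc_counts"), min_cells >= 0)
  keep <- rowSums(counts$counts > 0) >= min_cells
  subset_counts(counts, genes = counts$gene_ids[keep])
}

#' Summary of detected genes per cell
#'
#' @param counts A `ctc_counts` object.
#' @param cells Character vector of cell ids to summarize (default all).
#' @return List with `median`, `min`, `max`, `mean`, `n_cells` and the
#'   per-cell vector `n_genes`.
#' @export
detection_summary <- function(counts, cells = NULL) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (is.null(cells)) cells <- counts$cell_ids
  if (!length(cells)) stop("detection_summary: empty cell subset")
  m <- subset_counts(counts, cells = cells)$counts
  n_genes <- colSums(m > 0)
  list(median = stats::median(n_genes), min = min(n_genes), max = max(n_genes),
       mean = mean(n_genes), n_cells = length(cells), n_genes = n_genes)
}
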