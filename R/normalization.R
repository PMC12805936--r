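#' Median-of-ratios size factors
#'
#' Per-cell scaling constants that normalize sequencing depth. In `standard`
#' mode the reference for gene g is the geometric mean of its counts across
#' all cells, computed over the genes positive in every cell, and the size
#' factor of cell j is the median over those genes of `k_gj / r_g`. Sparse
#' single-cell matrices rarely have enough all-positive genes, so the default
#' `positive` mode computes the reference of each gene over the cells where it
#' is positive, `r_g = exp(mean(log k_gj | k_gj > 0))`, and takes the per-cell
#' median over that cell's positive genes. In both modes the factors are
#' rescaled so their geometric mean is 1, which fixes the arbitrary overall
#' scale. For an all-positive matrix the two modes agree exactly.
#'
#' @param counts A `ctc_counts` object or a plain numeric matrix (genes x
#'   cells).
#' @param mode `"positive"` (default) or `"standard"`.
#' @return Named numeric vector of positive size factors, one per cell,
#'   geometric mean 1.
#' @export
size_factors <- function(counts, mode = c("positive", "standard")) {
  mode <- match.arg(mode)
  m <- if (inherits(counts, "ctc_counts")) counts$counts else as.matrix(counts)
  if (ncol(m) < 1) stop("size_factors: no cells")
  if (mode == "standard") {
    usable <- rowSums(m > 0) == ncol(m)
    if (!any(usable)) {
      stop("size_factors: no gene is positive in every cell; ",
           "use mode = \"positive\"")
    }
    sub <- m[usable, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    s <- apply(sub, 2, function(k) stats::median(k / ref))
  } else {
    pos <- m > 0
    usable <- rowSums(pos) > 0
    if (!any(usable)) stop("size_factors: all-zero matrix")
    sub <- m[usable, , drop = FALSE]
    possub <- pos[usable, , drop = FALSE]
    logm <- ifelse(possub, log(sub), 0)
    ref <- exp(rowSums(logm) / rowSums(possub))
    s <- vapply(seq_len(ncol(sub)), function(j) {
      use <- possub[, j]
      if (!any(use)) {
        stop("size_factors: cell '", colnames(m)[j], "' has no positive counts")
      }
      stats::median(sub[use, j] / ref[use])
    }, numeric(1))
  }
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(m)
  s
}

#' Normalize counts by size factors and log-transform
#'
#' Produces the normalized linear scale `x_gj = k_gj / s_j` and the log scale
#' `y_gj = log2(x_gj + 1)` (pseudocount fixed at 1); both matrices are kept.
#'
#' @param counts A `ctc_counts` object.
#' @param sf Size factors from [size_factors()]; computed with the default
#'   mode when omitted.
#' @return A `ctc_norm` object: list with `normalized`, `log2`,
#'   `size_factors`, `gene_ids`, `cell_ids`.
#' @export
normalize_log2 <- function(counts, sf = NULL) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (is.null(sf)) sf <- size_factors(counts)
  if (!all(counts$cell_ids %in% names(sf))) {
    stop("size factors missing for some cells")
  }
  sf <- sf[counts$cell_ids]
  if (any(sf <= 0)) stop("size factors must be positive")
  x <- sweep(counts$counts, 2, sf, "/")
  structure(list(normalized = x, log2 = log2(x + 1), size_factors = sf,
                 gene_ids = counts$gene_ids, cell_ids = counts$cell_ids),
            class = "ctc_norm")
}

#' Per-gene mean normalized expression
#'
#' The cascade's expression statistic: the arithmetic mean of size-factor
#' normalized counts over a cell subset, on the linear scale by default (the
#' log2 scale is available behind `scale = "log2"`).
#'
#' @param norm A `ctc_norm` object from [normalize_log2()].
#' @param cells Cell ids to average over (default all).
#' @param scale `"linear"` (default) or `"log2"`.
#' @return Named numeric vector, one mean per gene.
#' @export
mean_normalized_expression <- function(norm, cells = NULL,
                                       scale = c("linear", "log2")) {
  stopifnot(inherits(norm, "ctc_norm"))
  scale <- match.arg(scale)
  if (is.null(cells)) cells <- norm$cell_ids
  if (!length(cells)) stop("mean_normalized_expression: empty cell subset")
  missing <- setdiff(cells, norm$cell_ids)
  if (length(missing)) stop("unknown cell id(s): ", paste(missing, collapse = ", "))
  m <- if (scale == "linear") norm$normalized else norm$log2
  rowMeans(m[, cells, drop = FALSE])
}
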