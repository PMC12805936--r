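#' Configuration of the candidate-marker filter cascade
#'
#' Thresholds follow the strict-inequality semantics of the screen: genes with
#' PBMC single-cell count strictly above `pbmc_count_max` are subtracted,
#' genes with whole-blood expression strictly above `blood_expr_max` (TPM-like
#' units) are removed, genes with mean normalized CTC expression strictly
#' below `min_mean_expr` are removed (or, in `percentile` mode, only the top
#' `top_pct` percent by mean expression are kept, ties at the cutoff all
#' retained), and genes detected in strictly less than `min_detect_frac` of
#' the CTCs are removed. Detection means raw count at least
#' `detection_min_count`.
#'
#' @param pbmc_count_max Maximum tolerated PBMC single-cell count; default 0
#'   (any PBMC expression disqualifies).
#' @param blood_expr_max Maximum whole-blood expression; default 15.
#' @param min_mean_expr Minimum mean normalized CTC expression; default 8
#'   (normalized linear units).
#' @param expression_mode `"threshold"` (default) or `"percentile"`.
#' @param top_pct Percent kept in percentile mode; default 5.
#' @param min_detect_frac Minimum detection fraction among CTCs; default 0.30.
#' @param detection_min_count Raw count defining detection; default 1.
#' @param required_biotype Biotype a candidate must have; default
#'   `"protein_coding"`.
#' @param required_location Subcellular location a candidate's location set
#'   must contain; default `"plasma_membrane"`.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(pbmc_count_max = 0, blood_expr_max = 15,
                           min_mean_expr = 8,
                           expression_mode = c("threshold", "percentile"),
                           top_pct = 5, min_detect_frac = 0.30,
                           detection_min_count = 1,
                           required_biotype = "protein_coding",
                           required_location = "plasma_membrane") {
  expression_mode <- match.arg(expression_mode)
  stopifnot(pbmc_count_max >= 0, blood_expr_max >= 0, min_mean_expr >= 0,
            top_pct > 0, top_pct <= 100,
            min_detect_frac >= 0, min_detect_frac <= 1,
            detection_min_count >= 1)
  structure(list(pbmc_count_max = pbmc_count_max,
                 blood_expr_max = blood_expr_max,
                 min_mean_expr = min_mean_expr,
                 expression_mode = expression_mode,
                 top_pct = top_pct,
                 min_detect_frac = min_detect_frac,
                 detection_min_count = detection_min_count,
                 required_biotype = required_biotype,
                 required_location = required_location),
            class = "cascade_config")
}

#' Genes with any expression over a cell subset
#'
#' Stage 1 of the cascade: drop genes whose mean raw count over the subset is
#' zero (equivalently, no nonzero count in any subset cell).
#'
#' @param counts A `ctc_counts` object.
#' @param cells Cell ids forming the subset (default all).
#' @return Character vector of surviving gene ids, matrix order.
#' @export
drop_unexpressed <- function(counts, cells = NULL) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (is.null(cells)) cells <- counts$cell_ids
  if (!length(cells)) stop("drop_unexpressed: empty cell subset")
  m <- subset_counts(counts, cells = cells)$counts
  counts$gene_ids[rowSums(m) > 0]
}

#' Subtract PBMC-expressed genes
#'
#' @param genes Character vector of candidate gene ids.
#' @param ref A `blood_reference`; missing genes count as 0.
#' @param max_count Genes with `pbmc_max_count` strictly above this are
#'   removed; default 0.
#' @return Surviving gene ids.
#' @export
subtract_pbmc_expressed <- function(genes, ref, max_count = 0) {
  v <- blood_lookup(ref, genes)$pbmc_max_count
  genes[v <= max_count]
}

#' Subtract genes expressed in whole blood
#'
#' @param genes Character vector of candidate gene ids.
#' @param ref A `blood_reference`; missing genes count as 0.
#' @param max_expr Genes with `blood_expression` strictly above this are
#'   removed; default 15 (a value of exactly 15 is kept).
#' @return Surviving gene ids.
#' @export
subtract_whole_blood <- function(genes, ref, max_expr = 15) {
  v <- blood_lookup(ref, genes)$blood_expression
  genes[v <= max_expr]
}

#' Filter genes on mean normalized CTC expression
#'
#' Threshold mode keeps genes whose mean is at least `min_mean_expr` (a mean
#' of exactly 8 survives the "< 8 removed" rule). Percentile mode keeps the
#' top `top_pct` percent of the *input set* by mean expression; all genes
#' tying the cutoff value are retained, so the survivor count can exceed the
#' nominal percentage.
#'
#' @param genes Character vector of candidate gene ids.
#' @param mean_expr Named per-gene means from [mean_normalized_expression()];
#'   must cover all `genes`.
#' @param cfg A `cascade_config`.
#' @return Surviving gene ids.
#' @export
filter_by_expression <- function(genes, mean_expr, cfg = cascade_config()) {
  missing <- setdiff(genes, names(mean_expr))
  if (length(missing)) {
    stop("mean_expr missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  v <- mean_expr[genes]
  if (cfg$expression_mode == "threshold") {
    genes[v >= cfg$min_mean_expr]
  } else {
    n_keep <- max(1L, ceiling(length(genes) * cfg$top_pct / 100))
    cutoff <- sort(v, decreasing = TRUE)[n_keep]
    genes[v >= cutoff]
  }
}

#' Filter genes on CTC detection fraction
#'
#' Keeps genes detected (raw count >= `detection_min_count`) in at least
#' `min_detect_frac` of the subset cells; a fraction of exactly 30% is kept.
#'
#' @param genes Character vector of candidate gene ids.
#' @param counts A `ctc_counts` object.
#' @param cells Cell subset over which detection is assessed.
#' @param cfg A `cascade_config`.
#' @return Surviving gene ids.
#' @export
filter_by_coverage <- function(genes, counts, cells = NULL,
                               cfg = cascade_config()) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (is.null(cells)) cells <- counts$cell_ids
  if (!length(cells)) stop("filter_by_coverage: empty cell subset")
  m <- subset_counts(counts, genes = genes, cells = cells)$counts
  frac <- rowSums(m >= cfg$detection_min_count) / length(cells)
  genes[frac >= cfg$min_detect_frac]
}

#' Keep protein-coding genes
#'
#' Genes absent from the annotation are removed (unknown biotype is not
#' evidence of a protein-coding gene) and reported via attribute
#' `"unannotated"`.
#'
#' @param genes Character vector of candidate gene ids.
#' @param ann A `gene_annotation`.
#' @param biotype Required biotype; default `"protein_coding"`.
#' @return Surviving gene ids (attribute `unannotated` lists genes dropped
#'   for missing annotation).
#' @export
filter_protein_coding <- function(genes, ann, biotype = "protein_coding") {
  look <- annotation_lookup(ann, genes)
  keep <- !is.na(look$biotype) & look$biotype == biotype
  out <- genes[keep]
  attr(out, "unannotated") <- genes[is.na(look$biotype)]
  out
}

#' Keep genes annotated to the plasma membrane
#'
#' Membership, not exclusivity: a gene located to both the plasma membrane
#' and the cytosol is kept. Genes with empty or missing location sets are
#' removed.
#'
#' @param genes Character vector of candidate gene ids.
#' @param ann A `gene_annotation`.
#' @param location Required location; default `"plasma_membrane"`.
#' @return Surviving gene ids (attribute `unannotated` as in
#'   [filter_protein_coding()]).
#' @export
filter_plasma_membrane <- function(genes, ann, location = "plasma_membrane") {
  look <- annotation_lookup(ann, genes)
  keep <- vapply(look$locations, function(l) location %in% l, logical(1))
  out <- genes[keep]
  attr(out, "unannotated") <- genes[is.na(look$biotype)]
  out
}

#' Apply the manual curation list
#'
#' The antibody-availability / surface-staining assessment is not computable;
#' it arrives as a user-supplied keep list that is intersected with the
#' surviving genes. Whitelist entries (established markers such as EGFR) are
#' appended and flagged `known = TRUE` even if absent from the keep list.
#'
#' @param genes Character vector of surviving gene ids.
#' @param keep_list Curated gene ids to retain.
#' @param whitelist Known-marker gene ids always appended (must have survived
#'   the cascade to be meaningful; appended regardless, flagged known).
#' @return Data frame with columns `gene`, `known`.
#' @export
apply_curation <- function(genes, keep_list, whitelist = character(0)) {
  absent <- setdiff(keep_list, genes)
  if (length(absent)) {
    warning("curation list gene(s) not in surviving set: ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  kept <- intersect(genes, keep_list)
  extra <- setdiff(whitelist, kept)
  data.frame(gene = c(kept, extra),
             known = c(kept %in% whitelist, rep(TRUE, length(extra))),
             stringsAsFactors = FALSE)
}

#' Run the full candidate-marker cascade
#'
#' Executes, in fixed order: drop unexpressed genes, subtract PBMC-expressed
#' genes, subtract whole-blood-expressed genes, filter on mean normalized
#' expression, filter on CTC detection fraction, keep protein-coding genes,
#' keep plasma-membrane genes, then apply the manual curation list. Each
#' stage's input and surviving gene sets are recorded; every stage output is a
#' subset of its input.
#'
#' @param counts A `ctc_counts` object (typically after cell and gene QC).
#' @param ref A `blood_reference`.
#' @param ann A `gene_annotation`.
#' @param cfg A `cascade_config`.
#' @param curation Character vector: the curated keep list (`NULL` skips the
#'   curation stage).
#' @param cells Cell subset feeding expression and coverage statistics
#'   (typically the CTCs only); default all cells.
#' @param mean_expr Optional precomputed named means from
#'   [mean_normalized_expression()]; computed from `counts` over `cells` with
#'   default-mode size factors when omitted.
#' @param whitelist Passed to [apply_curation()].
#' @return A `cascade_result`: list with `stages` (each: `name`, `n_in`,
#'   `n_out`, `genes`), `candidates` (data frame `gene`, `known`), `config`.
#' @export
run_cascade <- function(counts, ref, ann, cfg = cascade_config(),
                        curation = NULL, cells = NULL, mean_expr = NULL,
                        whitelist = character(0)) {
  stopifnot(inherits(counts, "ctc_counts"))
  if (is.null(cells)) cells <- counts$cell_ids
  if (is.null(mean_expr)) {
    norm <- normalize_log2(counts)
    mean_expr <- mean_normalized_expression(norm, cells = cells)
  }
  stages <- list()
  record <- function(name, input, output) {
    stages[[length(stages) + 1L]] <<- list(name = name,
                                           n_in = length(input),
                                           n_out = length(output),
                                           genes = as.character(output))
    as.character(output)
  }
  run_stage <- function(name, input, f) {
    out <- tryCatch(f(input), error = function(e) {
      stop(sprintf("cascade stage '%s' failed: %s", name, conditionMessage(e)))
    })
    record(name, input, out)
  }
  g <- run_stage("expressed", counts$gene_ids,
                 function(gs) drop_unexpressed(counts, cells))
  g <- run_stage("pbmc_subtraction", g,
                 function(gs) subtract_pbmc_expressed(gs, ref, cfg$pbmc_count_max))
  g <- run_stage("whole_blood_subtraction", g,
                 function(gs) subtract_whole_blood(gs, ref, cfg$blood_expr_max))
  g <- run_stage("expression_filter", g,
                 function(gs) filter_by_expression(gs, mean_expr, cfg))
  g <- run_stage("coverage_filter", g,
                 function(gs) filter_by_coverage(gs, counts, cells, cfg))
  g <- run_stage("protein_coding", g,
                 function(gs) filter_protein_coding(gs, ann, cfg$required_biotype))
  g <- run_stage("plasma_membrane", g,
                 function(gs) filter_plasma_membrane(gs, ann, cfg$required_location))
  if (is.null(curation)) {
    candidates <- data.frame(gene = g, known = g %in% whitelist,
                             stringsAsFactors = FALSE)
  } else {
    candidates <- apply_curation(g, curation, whitelist)
    record("curation", g, candidates$gene)
  }
  structure(list(stages = stages, candidates = candidates,
                 config = unclass(cfg)),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("candidate-marker cascade:\n")
  for (s in x$stages) {
    cat(sprintf("  %-24s %6d -> %6d\n", s$name, s$n_in, s$n_out))
  }
  cat(sprintf("final candidates: %d (%d known)\n",
              nrow(x$candidates), sum(x$candidates$known)))
  invisible(x)
}

#' Per-stage survivor counts of a cascade result
#'
#' @param x A `cascade_result`.
#' @return Data frame with `stage`, `n_in`, `n_out`.
#' @export
cascade_counts <- function(x) {
  stopifnot(inherits(x, "cascade_result"))
  data.frame(stage = vapply(x$stages, `[[`, "", "name"),
             n_in = vapply(x$stages, `[[`, 0L, "n_in"),
             n_out = vapply(x$stages, `[[`, 0L, "n_out"),
             stringsAsFactors = FALSE)
}
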