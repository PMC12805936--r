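#' Marker-panel definitions
#'
#' The three cocktails assessed by the screen: the published markers
#' (EpCAM, HER2, EGFR), the four new markers (AHNAK2, CAVIN1, ODR4, TRIML2)
#' and their union.
#'
#' @return Named list of character vectors `published`, `new`, `total`.
#' @export
default_panels <- function() {
  published <- c("EPCAM", "HER2", "EGFR")
  new <- c("AHNAK2", "CAVIN1", "ODR4", "TRIML2")
  list(published = published, new = new, total = union(published, new))
}

#' Run the full screen end-to-end
#'
#' Executes, in order: per-cell QC (mapping and mitochondrial filters), the
#' gene filter, size-factor normalization, the candidate-marker cascade over
#' the CTC subset, and panel detection statistics. Deterministic for fixed
#' inputs. Any stage failure aborts with the stage name.
#'
#' @param counts A `ctc_counts` with `cell_groups` distinguishing `"CTC"`
#'   from control cells (cells without a group are treated as CTCs).
#' @param align_stats Alignment-statistics data frame (see
#'   [read_alignment_stats()]).
#' @param blood_ref A `blood_reference`.
#' @param annotation A `gene_annotation`.
#' @param curation Curated keep list for the final cascade stage (`NULL`
#'   skips curation).
#' @param qc A `qc_thresholds`.
#' @param cascade A `cascade_config`.
#' @param panels Named list of marker panels; defaults to [default_panels()].
#'   Panels with members absent from the filtered matrix are reported as
#'   `NULL` with a warning.
#' @param whitelist Known markers appended by curation; default `"EGFR"`.
#' @param sf_mode Size-factor mode, see [size_factors()].
#' @param report_path Optional path: write the JSON screen report there.
#' @return A `screen_report` list: `qc` (kept/removed/summary), `cells`
#'   (the CTC subset used), `size_factors`, `detection`, `cascade`
#'   (a `cascade_result`), `panels` (per-panel `panel_stats`), `candidates`.
#' @export
run_full_screen <- function(counts, align_stats, blood_ref, annotation,
                            curation = NULL, qc = qc_thresholds(),
                            cascade = cascade_config(),
                            panels = default_panels(),
                            whitelist = "EGFR", sf_mode = "positive",
                            report_path = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("screen stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  stopifnot(inherits(counts, "ctc_counts"))

  cell_qc <- stage("qc", compute_cell_qc(counts, align_stats))
  flt <- stage("qc", filter_cells(cell_qc, qc))
  kept_counts <- stage("qc", subset_counts(counts, cells = flt$kept))
  kept_counts <- stage("gene_filter",
                       filter_genes(kept_counts, qc$min_cells_per_gene))

  groups <- counts$cell_groups
  ctc_cells <- if (is.null(groups)) {
    flt$kept
  } else {
    intersect(flt$kept, names(groups)[groups == "CTC"])
  }
  if (!length(ctc_cells)) stop("screen stage 'qc' failed: no CTCs passed QC")

  det <- stage("detection_summary", detection_summary(kept_counts, ctc_cells))
  sf <- stage("normalization", size_factors(kept_counts, mode = sf_mode))
  norm <- stage("normalization", normalize_log2(kept_counts, sf))
  mean_expr <- stage("normalization",
                     mean_normalized_expression(norm, cells = ctc_cells))

  casc <- stage("cascade",
                run_cascade(kept_counts, blood_ref, annotation, cascade,
                            curation = curation, cells = ctc_cells,
                            mean_expr = mean_expr, whitelist = whitelist))

  panel_stats <- lapply(names(panels), function(nm) {
    genes <- panels[[nm]]
    missing <- setdiff(genes, kept_counts$gene_ids)
    if (length(missing)) {
      warning("panel '", nm, "' has gene(s) absent from the matrix: ",
              paste(missing, collapse = ", "), "; panel skipped")
      return(NULL)
    }
    panel_coverage(kept_counts, genes, ctc_cells,
                   min_count = cascade$detection_min_count)
  })
  names(panel_stats) <- names(panels)

  cand <- casc$candidates
  cand_stats <- if (nrow(cand)) {
    stage("panels", candidate_summary(kept_counts, cand$gene, ctc_cells,
                                      min_count = cascade$detection_min_count))
  } else NULL

  qc_summary <- list(
    n_cells_in = length(counts$cell_ids),
    n_cells_kept = length(flt$kept),
    n_ctc = length(ctc_cells),
    removed = lapply(seq_len(nrow(flt$removed)), function(i) {
      list(cell_id = flt$removed$cell_id[i],
           reasons = I(flt$removed$reasons[[i]]))
    }),
    n_genes_after_filter = length(kept_counts$gene_ids),
    detection = det[c("median", "min", "max", "mean")]
  )

  report <- structure(list(qc = list(cell_qc = cell_qc, kept = flt$kept,
                                     removed = flt$removed,
                                     summary = qc_summary),
                           cells = ctc_cells, size_factors = sf,
                           detection = det, mean_expr = mean_expr,
                           cascade = casc, panels = panel_stats,
                           candidates = cand,
                           candidate_stats = cand_stats),
                      class = "screen_report")
  if (!is.null(report_path)) {
    write_screen_report(casc, qc_summary, report_path)
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$qc$summary
  cat(sprintf("screen: %d cells in, %d kept (%d CTCs); %d genes after filter\n",
              s$n_cells_in, s$n_cells_kept, s$n_ctc, s$n_genes_after_filter))
  cat(sprintf("median detected genes per CTC: %s\n", s$detection$median))
  print(x$cascade)
  invisible(x)
}

#' Quantify validation staining across images and event tables
#'
#' For each image: segment on the nuclear channel, measure mean gray values,
#' classify cells, and compute the percent of the target population positive
#' for the marker channel. The pooled percentage is the cell-weighted
#' aggregate (total positive over total population). Event tables are gated
#' and their marker-positive fractions reported.
#'
#' @param stacks Named list of `image_stack` objects (may be empty).
#' @param events Named list of event data frames (may be empty).
#' @param seg A `segmentation_config`.
#' @param scheme A `class_scheme`.
#' @param population Target class; default `"ctc"`.
#' @param marker_channel,marker_cutoff Positivity definition for the marker
#'   channel.
#' @param gate A `gate_config` (required when `events` are supplied).
#' @return List with `per_image` (data frame), `pooled_percent`,
#'   `class_counts` (per-image class tallies) and `flow` (per-table gating
#'   results).
#' @export
run_validation_quant <- function(stacks = list(), events = list(),
                                 seg = segmentation_config(),
                                 scheme, population = "ctc",
                                 marker_channel = "marker",
                                 marker_cutoff = 0.4, gate = NULL) {
  if (!length(stacks) && !length(events)) {
    stop("run_validation_quant: no images and no event tables supplied")
  }
  per_image <- NULL
  class_counts <- list()
  tot_pos <- 0L; tot_pop <- 0L
  if (length(stacks)) {
    stopifnot(inherits(scheme, "class_scheme"))
    rows <- lapply(names(stacks), function(nm) {
      st <- stacks[[nm]]
      labels <- segment_nuclei(st, seg)
      meas <- measure_cells(labels, st)
      classes <- classify_cells(meas, scheme)
      class_counts[[nm]] <<- table(factor(classes,
                                          levels = c(names(scheme$rules),
                                                     "ambiguous")))
      pp <- percent_positive(meas, classes, population, marker_channel,
                             marker_cutoff)
      tot_pos <<- tot_pos + pp$n_positive
      tot_pop <<- tot_pop + pp$n_population
      data.frame(image = nm, n_cells = nrow(meas),
                 n_population = pp$n_population, n_positive = pp$n_positive,
                 percent_positive = pp$percent, stringsAsFactors = FALSE)
    })
    per_image <- do.call(rbind, rows)
  }
  flow <- NULL
  if (length(events)) {
    if (is.null(gate)) stop("run_validation_quant: gate config required for events")
    flow <- lapply(events, gate_events, cfg = gate)
  }
  list(per_image = per_image,
       pooled_percent = if (tot_pop > 0) 100 * tot_pos / tot_pop else NA_real_,
       class_counts = class_counts, flow = flow)
}
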