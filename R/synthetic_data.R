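# Generators that emulate the study's inputs with exact ground truth, so every
# pipeline stage can be exercised and validated offline.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
                "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
                "MT-CYB")

# True markers are the candidate names reported for this screen; EGFR is the
# established marker that re-emerges from the cascade. Decoys each violate
# exactly one cascade stage: PTPRC (CD45) is PBMC-expressed, HBB is
# whole-blood-high, HER2 is dimly expressed, EPCAM is detected in too few
# CTCs, DECOY_NONCODING is a lincRNA, DECOY_CYTOSOL lacks a plasma-membrane
# location, ATP23 passes every computable filter but fails manual curation,
# DECOY_UNEXPR has no counts at all.
TRUE_MARKERS <- c("AHNAK2", "CAVIN1", "ODR4", "TRIML2", "S100A16", "EGFR")
DECOY_CLASSES <- c(PTPRC = "decoy_pbmc", HBB = "decoy_blood",
                   HER2 = "decoy_lowexpr", EPCAM = "decoy_lowcov",
                   DECOY_NONCODING = "decoy_biotype",
                   DECOY_CYTOSOL = "decoy_location",
                   ATP23 = "decoy_curation",
                   DECOY_UNEXPR = "decoy_unexpressed")

#' Configuration for the synthetic CTC study
#'
#' Defaults mirror the study design: 37 CTCs passing quality control out of a
#' 41-cell cohort (3 cells planted below the 50% unique-mapping bound, 1 cell
#' above the 50% mitochondrial bound), 6 cultured control cells, and a
#' transcriptome-scale gene set. Planted detection fractions for the
#' published markers reproduce the study's detection pattern (EPCAM 8/37,
#' HER2 17/37, EGFR 33/37, with exactly 3 CTCs negative for all three), and
#' the 6 true markers are each detected in at least 45% of the CTCs.
#'
#' @param n_ctc Number of CTCs that pass QC; default 37.
#' @param n_control Number of cultured control cells; default 6.
#' @param n_map_fail,n_mito_fail Planted QC failures among the raw CTC
#'   cohort; defaults 3 and 1.
#' @param n_genes Total gene count including markers, decoys and
#'   mitochondrial genes; default 20000.
#' @param bg_meanlog,bg_sdlog Log-normal parameters of background gene means;
#'   defaults 0.2 and 2.2 (full-length single-cell scale: a median of several
#'   thousand detected genes per cell).
#' @param bg_size Negative-binomial dispersion (size) of background genes;
#'   default 0.25.
#' @param depth_sdlog Log-normal spread of per-cell sequencing depth factors;
#'   default 0.25.
#' @param mito_frac Expected mitochondrial fraction in healthy cells;
#'   default 0.10.
#' @param marker_detect_frac Named planted detection fractions (of kept CTCs)
#'   for the six true markers.
#' @param seed Integer seed; every generator is a pure function of
#'   config + seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ctc = 37, n_control = 6, n_map_fail = 3,
                       n_mito_fail = 1, n_genes = 20000,
                       bg_meanlog = 0.2, bg_sdlog = 2.2, bg_size = 0.25,
                       depth_sdlog = 0.25, mito_frac = 0.10,
                       marker_detect_frac = c(AHNAK2 = 30 / 37,
                                              CAVIN1 = 34 / 37,
                                              ODR4 = 17 / 37,
                                              TRIML2 = 24 / 37,
                                              S100A16 = 33 / 37,
                                              EGFR = 33 / 37),
                       seed = 1L) {
  stopifnot(n_ctc >= 1, n_control >= 1, n_map_fail >= 0, n_mito_fail >= 0,
            all(marker_detect_frac > 0 & marker_detect_frac <= 1),
            setequal(names(marker_detect_frac), TRUE_MARKERS))
  n_special <- length(TRUE_MARKERS) + length(DECOY_CLASSES) + length(MITO_GENES)
  if (n_genes < n_special + 10) {
    stop("n_genes must exceed ", n_special + 10,
         " (markers, decoys, mitochondrial genes plus background)")
  }
  structure(list(n_ctc = n_ctc, n_control = n_control,
                 n_map_fail = n_map_fail, n_mito_fail = n_mito_fail,
                 n_genes = n_genes, bg_meanlog = bg_meanlog,
                 bg_sdlog = bg_sdlog, bg_size = bg_size,
                 depth_sdlog = depth_sdlog, mito_frac = mito_frac,
                 marker_detect_frac = marker_detect_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# counts for cells where a strong (threshold-clearing) gene is detected:
# a floor well above the expression cutoff plus negative-binomial noise.
strong_counts <- function(n) 50 + stats::rnbinom(n, mu = 30, size = 2)
# dim counts: detected but far below the mean-expression cutoff.
dim_counts <- function(n) 1 + stats::rnbinom(n, mu = 2, size = 2)

#' Simulate the CTC count matrix, alignment statistics and ground truth
#'
#' Counts are negative-binomial per gene class with per-cell depth factors;
#' zeros arise from low means, not a separate dropout process. Planted QC
#' failures: `n_map_fail` CTCs receive a uniquely-mapped percentage below
#' 50%, and `n_mito_fail` CTCs have their mitochondrial counts inflated above
#' 50% of their total. Marker and decoy genes receive exact planted
#' detected-cell sets among the QC-passing CTCs, so every cascade contract
#' holds by construction for any seed.
#'
#' @param cfg A `sim_config`.
#' @return List with `counts` (a `ctc_counts` over the raw cohort plus
#'   controls), `align_stats` (data frame), `truth` (list with `gene_table`
#'   and `cell_table`).
#' @export
simulate_ctc_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_raw <- cfg$n_ctc + cfg$n_map_fail + cfg$n_mito_fail
    ctc_ids <- sprintf("CTC%02d", seq_len(n_raw))
    ctl_ids <- sprintf("LM2_%02d", seq_len(cfg$n_control))
    cell_ids <- c(ctc_ids, ctl_ids)
    n_cells <- length(cell_ids)

    fail_map <- if (cfg$n_map_fail) sample(ctc_ids, cfg$n_map_fail) else character(0)
    fail_mito <- if (cfg$n_mito_fail) {
      sample(setdiff(ctc_ids, fail_map), cfg$n_mito_fail)
    } else character(0)
    kept_ctc <- setdiff(ctc_ids, c(fail_map, fail_mito))
    n_kept <- length(kept_ctc)

    special <- c(TRUE_MARKERS, names(DECOY_CLASSES))
    n_bg <- cfg$n_genes - length(special) - length(MITO_GENES)
    bg_ids <- sprintf("BG%05d", seq_len(n_bg))
    gene_ids <- c(special, MITO_GENES, bg_ids)

    depth <- stats::rlnorm(n_cells, 0, cfg$depth_sdlog)
    names(depth) <- cell_ids

    counts <- matrix(0, nrow = length(gene_ids), ncol = n_cells,
                     dimnames = list(gene_ids, cell_ids))

    # background genes: NB(mu_g * depth_j, size)
    bg_mu <- stats::rlnorm(n_bg, cfg$bg_meanlog, cfg$bg_sdlog)
    counts[bg_ids, ] <- stats::rnbinom(n_bg * n_cells,
                                       mu = outer(bg_mu, depth),
                                       size = cfg$bg_size)

    # mitochondrial genes sized to land near mito_frac of the background total
    mito_mu <- sum(bg_mu) * cfg$mito_frac / (1 - cfg$mito_frac) / length(MITO_GENES)
    counts[MITO_GENES, ] <- stats::rnbinom(length(MITO_GENES) * n_cells,
                                           mu = outer(rep(mito_mu, length(MITO_GENES)), depth),
                                           size = 5)

    # planted detection sets among kept CTCs ------------------------------
    plant <- function(gene, cells, draw) {
      counts[gene, cells] <<- draw(length(cells))
    }
    det_n <- function(frac) max(1L, min(n_kept, round(frac * n_kept)))

    # published markers: EGFR (true marker), EPCAM (coverage decoy, strong
    # counts in few cells), HER2 (expression decoy, dim counts), arranged so
    # a fixed number of kept CTCs are negative for all three.
    n_egfr <- det_n(cfg$marker_detect_frac[["EGFR"]])
    egfr_cells <- sample(kept_ctc, n_egfr)
    non_egfr <- setdiff(kept_ctc, egfr_cells)
    n_triple_neg <- max(0L, length(non_egfr) - 1L)
    covered_extra <- if (length(non_egfr)) {
      sample(non_egfr, length(non_egfr) - n_triple_neg)
    } else character(0)
    triple_neg <- setdiff(non_egfr, covered_extra)
    n_her2 <- det_n(17 / 37)
    her2_cells <- unique(c(covered_extra,
                           sample(egfr_cells, min(n_her2 - length(covered_extra),
                                                  length(egfr_cells)))))
    n_epcam <- det_n(8 / 37)
    epcam_pool <- setdiff(kept_ctc, triple_neg)
    epcam_cells <- sample(epcam_pool, min(n_epcam, length(epcam_pool)))

    plant("EGFR", egfr_cells, strong_counts)
    plant("HER2", her2_cells, dim_counts)
    plant("EPCAM", epcam_cells, strong_counts)

    # remaining true markers: planted detection fractions, strong counts
    for (g in setdiff(TRUE_MARKERS, "EGFR")) {
      plant(g, sample(kept_ctc, det_n(cfg$marker_detect_frac[[g]])),
            strong_counts)
    }
    # decoys that must pass expression and coverage
    plant("PTPRC", sample(kept_ctc, det_n(30 / 37)), strong_counts)
    plant("HBB", sample(kept_ctc, det_n(25 / 37)), strong_counts)
    plant("DECOY_NONCODING", sample(kept_ctc, det_n(28 / 37)), strong_counts)
    plant("DECOY_CYTOSOL", sample(kept_ctc, det_n(26 / 37)), strong_counts)
    plant("ATP23", sample(kept_ctc, det_n(20 / 37)), strong_counts)
    # DECOY_UNEXPR stays all-zero

    # controls: cultured tumor cells express the markers broadly
    for (g in setdiff(special, c("DECOY_UNEXPR", "PTPRC"))) {
      plant(g, ctl_ids, strong_counts)
    }

    # mitochondrial-failure cells: inflate MT counts above half the total
    for (cell in fail_mito) {
      non_mito <- sum(counts[setdiff(gene_ids, MITO_GENES), cell])
      counts[MITO_GENES, cell] <- stats::rmultinom(
        1, size = ceiling(1.5 * non_mito), prob = rep(1, length(MITO_GENES)))
    }

    map_pct <- stats::runif(n_cells, 70, 95)
    names(map_pct) <- cell_ids
    map_pct[fail_map] <- stats::runif(length(fail_map), 20, 45)

    align_stats <- data.frame(
      cell_id = cell_ids,
      unique_map_pct = as.numeric(map_pct),
      total_reads = round(depth * 1.8e6),
      stringsAsFactors = FALSE)

    gene_class <- c(stats::setNames(rep("true_marker", length(TRUE_MARKERS)),
                                    TRUE_MARKERS),
                    DECOY_CLASSES,
                    stats::setNames(rep("mito", length(MITO_GENES)), MITO_GENES),
                    stats::setNames(rep("background", n_bg), bg_ids))
    det_frac <- rowSums(counts[, kept_ctc, drop = FALSE] > 0) / n_kept
    truth <- list(
      gene_table = data.frame(gene_id = gene_ids,
                              class = as.character(gene_class[gene_ids]),
                              detect_frac_ctc = as.numeric(det_frac),
                              stringsAsFactors = FALSE, row.names = NULL),
      cell_table = data.frame(
        cell_id = cell_ids,
        group = c(rep("CTC", n_raw), rep("control", cfg$n_control)),
        planted_fail = ifelse(cell_ids %in% fail_map, "mapping",
                              ifelse(cell_ids %in% fail_mito, "mito", "none")),
        stringsAsFactors = FALSE),
      kept_ctc = kept_ctc)

    groups <- stats::setNames(truth$cell_table$group, cell_ids)
    list(counts = count_matrix(counts, gene_ids, cell_ids, groups),
         align_stats = align_stats, truth = truth)
  })
}

#' Simulate blood-reference and annotation tables consistent with the truth
#'
#' Reference values honor each gene class's contract: true markers are
#' PBMC-negative, whole-blood-low, protein-coding and plasma-membrane;
#' each decoy violates exactly its own filter; every background gene carries
#' at least one disqualifying property (PBMC expression, high whole-blood
#' expression, a non-coding biotype, or a non-membrane location) with a
#' realistic mix, so the cascade's ground truth is exact.
#'
#' @param cfg A `sim_config`.
#' @param truth Truth list from [simulate_ctc_counts()].
#' @return List with `blood_ref` (a `blood_reference`) and `annotation`
#'   (a `gene_annotation`).
#' @export
simulate_references <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    gt <- truth$gene_table
    n <- nrow(gt)
    pbmc <- numeric(n)
    blood <- stats::runif(n, 0, 15)
    biotype <- rep("protein_coding", n)
    locations <- rep(list("plasma_membrane"), n)

    cls <- gt$class
    idx <- function(cl) which(cls == cl)

    pbmc[idx("decoy_pbmc")] <- stats::runif(length(idx("decoy_pbmc")), 1, 50)
    blood[idx("decoy_blood")] <- stats::runif(length(idx("decoy_blood")), 20, 2000)
    biotype[idx("decoy_biotype")] <- "lincRNA"
    locations[idx("decoy_location")] <- list("cytosol")

    mi <- idx("mito")
    pbmc[mi] <- stats::runif(length(mi), 10, 200)
    locations[mi] <- list("mitochondria")

    bg <- idx("background")
    mode <- sample(c("pbmc", "blood", "biotype", "location"), length(bg),
                   replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
    pbmc[bg[mode == "pbmc"]] <- stats::runif(sum(mode == "pbmc"), 0.5, 100)
    blood[bg[mode == "blood"]] <- stats::runif(sum(mode == "blood"), 15.5, 500)
    biotype[bg[mode == "biotype"]] <- sample(
      c("lincRNA", "pseudogene", "miRNA", "snoRNA"),
      sum(mode == "biotype"), replace = TRUE)
    locations[bg[mode == "location"]] <- sample(
      list("cytosol", "nucleus", c("nucleus", "cytosol"), "endoplasmic_reticulum"),
      sum(mode == "location"), replace = TRUE)

    list(blood_ref = blood_reference(gt$gene_id, pbmc, blood),
         annotation = gene_annotation(gt$gene_id, gt$gene_id, biotype,
                                      locations))
  })
}

#' Simulate the complete study bundle
#'
#' Counts, alignment statistics, blood reference, gene annotation, the
#' curation keep list (the true markers — the stand-in for the manual
#' antibody assessment) and the known-marker whitelist, all mutually
#' consistent.
#'
#' @param cfg A `sim_config`.
#' @return List with `counts`, `align_stats`, `blood_ref`, `annotation`,
#'   `curation`, `whitelist`, `truth`.
#' @export
simulate_full_study <- function(cfg = sim_config()) {
  sim <- simulate_ctc_counts(cfg)
  refs <- simulate_references(cfg, sim$truth)
  list(counts = sim$counts, align_stats = sim$align_stats,
       blood_ref = refs$blood_ref, annotation = refs$annotation,
       curation = TRUE_MARKERS, whitelist = "EGFR", truth = sim$truth)
}

#' Simulate a multi-channel immunofluorescence image with ground truth
#'
#' Places non-overlapping disk-shaped cells on a grid. The nuclear channel is
#' bright inside every disk; the tag channel is bright on tumor-class cells,
#' the CD45 channel on immune-class cells, and the marker channel on the
#' planted marker-positive subset of tumor-class cells. Positive and negative
#' intensities are separated by a large factor (0.8 vs 0.05) so that with
#' moderate noise classification remains exact. An exact number of
#' tumor-class cells, `round(frac_marker_positive * n_ctc)`, is planted
#' marker-positive; the realized fraction is recorded in the truth table.
#'
#' @param n_ctc,n_immune Numbers of tumor-class (tag+/CD45-) and immune-class
#'   (CD45+/tag-) cells.
#' @param frac_marker_positive Planted marker-positive fraction among
#'   tumor-class cells.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensities clamped to \[0, 1\]); default 0.
#' @param radius Disk radius in pixels; default 4.
#' @param seed Integer seed.
#' @return List with `stack` (an `image_stack`), `truth` (data frame `cell`,
#'   `centroid_row`, `centroid_col`, `class`, `marker_positive`) and
#'   `realized_fraction`.
#' @export
simulate_if_image <- function(n_ctc, n_immune, frac_marker_positive,
                              noise_sd = 0, radius = 4, seed = 1L) {
  stopifnot(n_ctc >= 0, n_immune >= 0, n_ctc + n_immune >= 1,
            frac_marker_positive >= 0, frac_marker_positive <= 1)
  with_seed(seed, {
    n <- n_ctc + n_immune
    pitch <- 4L * radius + 2L
    grid <- ceiling(sqrt(n))
    side <- grid * pitch + pitch
    centers_row <- pitch + ((seq_len(n) - 1) %% grid) * pitch
    centers_col <- pitch + ((seq_len(n) - 1) %/% grid) * pitch

    classes <- sample(c(rep("ctc", n_ctc), rep("immune", n_immune)))
    n_pos <- round(frac_marker_positive * n_ctc)
    ctc_idx <- which(classes == "ctc")
    marker_pos <- logical(n)
    if (n_pos > 0) marker_pos[sample(ctc_idx, n_pos)] <- TRUE

    bgv <- 0.02; hi <- 0.8; lo <- 0.05
    ch <- function() matrix(bgv, nrow = side, ncol = side)
    nuclear <- ch(); tag <- ch(); cd45 <- ch(); marker <- ch()
    rr <- seq(-radius, radius)
    disk <- outer(rr, rr, function(a, b) a^2 + b^2 <= radius^2)
    for (i in seq_len(n)) {
      ri <- centers_row[i] + rr; ci <- centers_col[i] + rr
      nuclear[ri, ci][disk] <- 0.85
      tag[ri, ci][disk] <- if (classes[i] == "ctc") hi else lo
      cd45[ri, ci][disk] <- if (classes[i] == "immune") hi else lo
      marker[ri, ci][disk] <- if (marker_pos[i]) hi else lo
    }
    channels <- list(nuclear = nuclear, tag = tag, cd45 = cd45, marker = marker)
    if (noise_sd > 0) {
      channels <- lapply(channels, function(x) {
        pmin(pmax(x + stats::rnorm(length(x), 0, noise_sd), 0), 1)
      })
    }
    truth <- data.frame(cell = seq_len(n), centroid_row = centers_row,
                        centroid_col = centers_col, class = classes,
                        marker_positive = marker_pos, stringsAsFactors = FALSE)
    list(stack = image_stack(channels), truth = truth,
         realized_fraction = if (n_ctc > 0) n_pos / n_ctc else NA_real_)
  })
}

#' Simulate a flow-cytometry-style event table with ground truth
#'
#' Gated-population events are tag-bright/CD45-dim; outside events the
#' reverse. Exactly `round(frac_marker_positive * n_gated)` gated events are
#' marker-bright.
#'
#' @param n_gated,n_outside Event counts inside and outside the tumor gate.
#' @param frac_marker_positive Planted marker-positive fraction within the
#'   gate.
#' @param noise_sd Additive Gaussian noise on intensities; default 0.
#' @param seed Integer seed.
#' @return List with `events` (data frame `event_id`, `tag`, `cd45`,
#'   `marker`), `truth` (per-event `gated`, `marker_positive`) and
#'   `realized_fraction`.
#' @export
simulate_flow_events <- function(n_gated, n_outside, frac_marker_positive,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(n_gated >= 0, n_outside >= 0,
            frac_marker_positive >= 0, frac_marker_positive <= 1)
  with_seed(seed, {
    n <- n_gated + n_outside
    gated <- sample(rep(c(TRUE, FALSE), c(n_gated, n_outside)))
    n_pos <- round(frac_marker_positive * n_gated)
    marker_pos <- logical(n)
    if (n_pos > 0) marker_pos[sample(which(gated), n_pos)] <- TRUE
    hi <- 0.8; lo <- 0.05
    mk <- function(v) {
      if (noise_sd > 0) pmax(v + stats::rnorm(n, 0, noise_sd), 0) else v
    }
    events <- data.frame(event_id = sprintf("E%05d", seq_len(max(n, 1))[seq_len(n)]),
                         tag = mk(ifelse(gated, hi, lo)),
                         cd45 = mk(ifelse(gated, lo, hi)),
                         marker = mk(ifelse(marker_pos, hi, lo)),
                         stringsAsFactors = FALSE)
    list(events = events,
         truth = data.frame(event_id = events$event_id, gated = gated,
                            marker_positive = marker_pos,
                            stringsAsFactors = FALSE),
         realized_fraction = if (n_gated > 0) n_pos / n_gated else NA_real_)
  })
}
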