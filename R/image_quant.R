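#' Construct a multi-channel image stack
#'
#' @param channels Named list of 2-D numeric matrices, one per channel (names
#'   conventionally drawn from `nuclear`, `tag`, `cd45`, `marker`, `panck`).
#'   All channels must share the same dimensions; intensities must be finite
#'   and non-negative.
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every channel must be a 2-D matrix")
  }
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must have identical dimensions")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch)) || any(ch < 0)) {
      stop("channel '", nm, "' must be finite and non-negative")
    }
  }
  structure(list(channels = channels, dim = dims[[1]]), class = "image_stack")
}

#' Read an image stack from a channel manifest
#'
#' The manifest is a YAML map from channel name to TIFF path (relative paths
#' resolved against the manifest's directory).
#'
#' @param manifest_path Path to the YAML manifest.
#' @return An `image_stack` object.
#' @export
read_image_stack <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  channels <- lapply(man, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    img <- tiff::readTIFF(full)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  image_stack(channels)
}

#' Write an image stack as per-channel TIFFs plus a manifest
#'
#' Intensities must lie in \[0, 1\] (the float TIFF convention used
#' throughout the package).
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return Invisibly, the manifest path.
#' @export
write_image_stack <- function(stack, dir, manifest = "channels.yaml") {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    if (max(ch) > 1) stop("channel '", nm, "' exceeds 1; TIFF output expects [0,1]")
    f <- paste0(nm, ".tif")
    tiff::writeTIFF(ch, file.path(dir, f), bits.per.sample = 32)
    files[[nm]] <- f
  }
  path <- file.path(dir, manifest)
  yaml::write_yaml(files, path)
  invisible(path)
}

#' Segmentation configuration
#'
#' @param nuclear_threshold Intensity cutoff on the nuclear channel, or
#'   `"otsu"` for automatic thresholding.
#' @param min_area Minimum object area in pixels; smaller components are
#'   discarded. Default 20.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#'   Default 4.
#' @param dilation_radius Radius (pixels) by which the nuclear mask is dilated
#'   before measurement, to capture membrane signal around nuclei. Default 0
#'   (no dilation).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(nuclear_threshold = 0.5, min_area = 20,
                                connectivity = 4, dilation_radius = 0) {
  stopifnot(min_area >= 1, connectivity %in% c(4, 8), dilation_radius >= 0)
  if (!identical(nuclear_threshold, "otsu")) {
    stopifnot(is.numeric(nuclear_threshold), nuclear_threshold >= 0)
  }
  structure(list(nuclear_threshold = nuclear_threshold, min_area = min_area,
                 connectivity = connectivity,
                 dilation_radius = dilation_radius),
            class = "segmentation_config")
}

# Run-based connected-component labeling with selectable connectivity.
# EBImage::bwlabel is 4-connected; the 8-connected variant merges row runs
# that touch diagonally via union-find.
label_components <- function(mask, connectivity = 4) {
  mask <- mask != 0
  if (connectivity == 4) {
    return(matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask))),
                  nrow = nrow(mask)))
  }
  nr <- nrow(mask)
  runs <- vector("list", nr)  # per row: matrix with columns start, end, id
  n_runs <- 0L
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (!length(on)) next
    ids <- n_runs + seq_along(on)
    n_runs <- n_runs + length(on)
    parent <- c(parent, ids)
    cur <- cbind(start = starts[on], end = ends[on], id = ids)
    if (i > 1 && !is.null(runs[[i - 1]])) {
      prev <- runs[[i - 1]]
      for (k in seq_len(nrow(cur))) {
        hit <- prev[, "start"] <= cur[k, "end"] + 1L &
               prev[, "end"] >= cur[k, "start"] - 1L
        for (p in prev[hit, "id"]) {
          ra <- find_root(p); rb <- find_root(cur[k, "id"])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    runs[[i]] <- cur
  }
  labels <- matrix(0L, nrow = nr, ncol = ncol(mask))
  if (n_runs == 0L) return(labels)
  roots <- vapply(seq_len(n_runs), find_root, integer(1))
  remap <- integer(n_runs)
  nxt <- 0L
  for (i in seq_len(nr)) {
    if (is.null(runs[[i]])) next
    cur <- runs[[i]]
    for (k in seq_len(nrow(cur))) {
      rt <- roots[cur[k, "id"]]
      if (remap[rt] == 0L) { nxt <- nxt + 1L; remap[rt] <- nxt }
      labels[i, cur[k, "start"]:cur[k, "end"]] <- remap[rt]
    }
  }
  labels
}

#' Segment nuclei from the nuclear channel
#'
#' Thresholds the nuclear channel at `nuclear_threshold` (pixels at or above
#' the cutoff are foreground), labels connected components, discards
#' components smaller than `min_area`, optionally dilates each object, and
#' returns an integer label matrix (background 0, objects renumbered 1..n).
#'
#' @param stack An `image_stack` with a `nuclear` channel.
#' @param cfg A `segmentation_config`.
#' @param nuclear_channel Name of the nuclear channel; default `"nuclear"`.
#' @return Integer matrix of labels.
#' @export
segment_nuclei <- function(stack, cfg = segmentation_config(),
                           nuclear_channel = "nuclear") {
  stopifnot(inherits(stack, "image_stack"))
  if (!nuclear_channel %in% names(stack$channels)) {
    stop("missing nuclear channel '", nuclear_channel, "'")
  }
  nuc <- stack$channels[[nuclear_channel]]
  thr <- cfg$nuclear_threshold
  if (identical(thr, "otsu")) {
    thr <- EBImage::otsu(EBImage::Image(nuc / max(max(nuc), 1)),
                         range = c(0, 1)) * max(max(nuc), 1)
  }
  mask <- nuc >= thr
  labels <- label_components(mask, cfg$connectivity)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    keep <- which(areas >= cfg$min_area)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  if (cfg$dilation_radius > 0 && max(labels) > 0) {
    brush <- EBImage::makeBrush(2 * cfg$dilation_radius + 1, shape = "disc")
    labels <- matrix(as.integer(EBImage::imageData(
      EBImage::dilate(EBImage::Image(labels), brush))), nrow = nrow(labels))
  }
  labels
}

#' Per-cell mean gray values
#'
#' For each labeled object: pixel area, centroid, and the mean intensity of
#' every channel over the object's mask pixels.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param stack An `image_stack` sharing the label matrix's dimensions.
#' @return Data frame with columns `label`, `area`, `centroid_row`,
#'   `centroid_col` and one mean-gray column per channel.
#' @export
measure_cells <- function(labels, stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(dim(labels), stack$dim)) {
    stop("label matrix and channels have different shapes")
  }
  idx <- which(labels > 0)
  if (!length(idx)) {
    out <- data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    for (nm in names(stack$channels)) out[[nm]] <- numeric(0)
    return(out)
  }
  f <- factor(labels[idx])
  lev <- as.integer(levels(f))
  area <- as.integer(table(f))
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  out <- data.frame(label = lev, area = area,
                    centroid_row = as.numeric(tapply(rows, f, mean)),
                    centroid_col = as.numeric(tapply(cols, f, mean)),
                    row.names = NULL)
  for (nm in names(stack$channels)) {
    out[[nm]] <- as.numeric(tapply(stack$channels[[nm]][idx], f, mean))
  }
  out
}

#' Classification scheme over per-channel positivity
#'
#' A cell is positive for a channel when its mean gray value is at or above
#' the channel's cutoff; cutoffs are uniform across all images of a batch.
#' Each rule demands positivity on its `pos` channels and negativity on its
#' `neg` channels. The default scheme encodes the CTC/immune rules: a CTC is
#' tag-positive and CD45-negative; an unambiguously immune cell is
#' CD45-positive and tag-negative.
#'
#' @param cutoffs Named numeric vector of per-channel cutoffs.
#' @param rules Named list; each element a list with character vectors `pos`
#'   and `neg` referencing channels present in `cutoffs`.
#' @return A `class_scheme` object.
#' @export
class_scheme <- function(cutoffs,
                         rules = list(
                           ctc = list(pos = "tag", neg = "cd45"),
                           immune = list(pos = "cd45", neg = "tag"))) {
  stopifnot(is.numeric(cutoffs), !is.null(names(cutoffs)))
  for (nm in names(rules)) {
    chans <- c(rules[[nm]]$pos, rules[[nm]]$neg)
    missing <- setdiff(chans, names(cutoffs))
    if (length(missing)) {
      stop("rule '", nm, "' references channel(s) without cutoffs: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(cutoffs = cutoffs, rules = rules), class = "class_scheme")
}

#' Classify segmented cells by rule
#'
#' Cells satisfying exactly one rule get that rule's name; cells satisfying no
#' rule, or more than one (conflicting positivity such as tag+/CD45+), are
#' labeled `"ambiguous"` and excluded from population denominators downstream.
#'
#' @param measurements Data frame from [measure_cells()].
#' @param scheme A `class_scheme`.
#' @return Character vector of class labels, one per row of `measurements`.
#' @export
classify_cells <- function(measurements, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  for (ch in names(scheme$cutoffs)) {
    if (!ch %in% names(measurements)) {
      stop("measurements lack channel '", ch, "'")
    }
  }
  positive <- sapply(names(scheme$cutoffs), function(ch) {
    measurements[[ch]] >= scheme$cutoffs[[ch]]
  })
  if (is.null(dim(positive))) positive <- matrix(positive, nrow = nrow(measurements),
                                                 dimnames = list(NULL, names(scheme$cutoffs)))
  vapply(seq_len(nrow(measurements)), function(i) {
    hits <- names(scheme$rules)[vapply(scheme$rules, function(rule) {
      all(positive[i, rule$pos]) && !any(positive[i, rule$neg])
    }, logical(1))]
    if (length(hits) == 1) hits else "ambiguous"
  }, character(1))
}

#' Percent of a population positive for a marker channel
#'
#' @param measurements Data frame from [measure_cells()].
#' @param classes Class labels from [classify_cells()].
#' @param population Class name defining the denominator (e.g. `"ctc"`).
#' @param marker_channel Channel assessed for positivity.
#' @param cutoff Positivity cutoff (mean gray value at or above is positive).
#' @return List with `percent`, `n_positive`, `n_population`.
#' @export
percent_positive <- function(measurements, classes, population,
                             marker_channel, cutoff) {
  stopifnot(length(classes) == nrow(measurements))
  in_pop <- classes == population
  if (!any(in_pop)) stop("empty population: '", population, "'")
  if (!marker_channel %in% names(measurements)) {
    stop("measurements lack channel '", marker_channel, "'")
  }
  pos <- measurements[[marker_channel]][in_pop] >= cutoff
  list(percent = 100 * sum(pos) / sum(in_pop),
       n_positive = sum(pos), n_population = sum(in_pop))
}

#' Rectangular gate configuration for event tables
#'
#' The gated population is tag-positive and CD45-negative (the tumor-tag /
#' leukocyte exclusion gate); marker positivity within the gate uses
#' `marker_cutoff`.
#'
#' @param tag_cutoff Events with `tag >= tag_cutoff` are tag-positive.
#' @param cd45_cutoff Events with `cd45 < cd45_cutoff` are CD45-negative.
#' @param marker_cutoff Events with `marker >= marker_cutoff` are
#'   marker-positive.
#' @return A `gate_config` list.
#' @export
gate_config <- function(tag_cutoff, cd45_cutoff, marker_cutoff) {
  stopifnot(is.finite(tag_cutoff), is.finite(cd45_cutoff),
            is.finite(marker_cutoff))
  structure(list(tag_cutoff = tag_cutoff, cd45_cutoff = cd45_cutoff,
                 marker_cutoff = marker_cutoff), class = "gate_config")
}

#' Gate an event table and quantify marker positivity
#'
#' @param events Data frame with numeric columns `tag`, `cd45`, `marker`.
#' @param cfg A `gate_config`.
#' @return List with `n_events`, `n_gated`, `n_marker_positive`, `fraction`
#'   (`NA` when the gate is empty) and `undefined` flag.
#' @export
gate_events <- function(events, cfg) {
  stopifnot(inherits(cfg, "gate_config"))
  need <- c("tag", "cd45", "marker")
  missing <- setdiff(need, names(events))
  if (length(missing)) stop("event table lacks channel(s): ",
                            paste(missing, collapse = ", "))
  if (nrow(events) && !all(vapply(events[need], function(v) all(is.finite(v)),
                                  logical(1)))) {
    stop("event intensities must be finite")
  }
  gated <- events$tag >= cfg$tag_cutoff & events$cd45 < cfg$cd45_cutoff
  n_gated <- sum(gated)
  if (n_gated == 0) {
    return(list(n_events = nrow(events), n_gated = 0L, n_marker_positive = 0L,
                fraction = NA_real_, undefined = TRUE))
  }
  n_pos <- sum(events$marker[gated] >= cfg$marker_cutoff)
  list(n_events = nrow(events), n_gated = n_gated, n_marker_positive = n_pos,
       fraction = n_pos / n_gated, undefined = FALSE)
}
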