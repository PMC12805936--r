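# Independent oracles, written as plain loops so they share no code path with
# the package implementations they check.

# Median-of-ratios size factors, positive-counts variant: the reference of
# each gene is the geometric mean of its positive counts; each cell's factor
# is the median ratio over its own positive genes; factors rescaled to
# geometric mean 1.
oracle_size_factors_positive <- function(m) {
  ref <- rep(NA_real_, nrow(m))
  for (g in seq_len(nrow(m))) {
    pos <- m[g, ][m[g, ] > 0]
    if (length(pos)) ref[g] <- exp(mean(log(pos)))
  }
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- c()
    for (g in seq_len(nrow(m))) {
      if (m[g, j] > 0) ratios <- c(ratios, m[g, j] / ref[g])
    }
    s[j] <- median(ratios)
  }
  s / exp(mean(log(s)))
}

# Standard variant: only genes positive in every cell contribute.
oracle_size_factors_standard <- function(m) {
  usable <- c()
  for (g in seq_len(nrow(m))) if (all(m[g, ] > 0)) usable <- c(usable, g)
  ref <- sapply(usable, function(g) exp(mean(log(m[g, ]))))
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s[j] <- median(m[usable, j] / ref)
  }
  s / exp(mean(log(s)))
}

# Flood-fill connected-component labeling (stack-based BFS).
oracle_label <- function(mask, connectivity = 4) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (sc in seq_len(nc)) for (sr in seq_len(nr)) {
    if (!mask[sr, sc] || lab[sr, sc] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(sr, sc))
    lab[sr, sc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Renumber labels by first occurrence in column-major order so two labelings
# of the same partition compare equal.
canonical_labels <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(lab)
  f <- lab[idx]
  map <- stats::setNames(seq_along(unique(f)), unique(f))
  out <- lab
  out[idx] <- as.integer(map[as.character(f)])
  out
}

# Small ctc_counts builder for hand-written matrices.
make_counts <- function(m, genes = NULL, cells = NULL, groups = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(m)))
  count_matrix(m, genes, cells, groups)
}

# Tiny annotation / reference builders.
make_annotation <- function(ids, biotype = "protein_coding",
                            locations = "plasma_membrane") {
  n <- length(ids)
  if (length(biotype) == 1) biotype <- rep(biotype, n)
  if (!is.list(locations)) locations <- rep(list(locations), n)
  gene_annotation(ids, ids, biotype, locations)
}

make_blood_ref <- function(ids, pbmc = 0, blood = 0) {
  n <- length(ids)
  blood_reference(ids, rep_len(pbmc, n), rep_len(blood, n))
}
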