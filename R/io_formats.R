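#' Construct a gene-by-cell count matrix
#'
#' The screen's substrate: raw integer counts with genes as rows and cells as
#' columns. Identifiers must be unique, counts non-negative integers.
#'
#' @param counts Numeric matrix, genes x cells. Values must be non-negative
#'   and integral (stored as double is fine).
#' @param gene_ids Character vector of gene identifiers (gene symbols are the
#'   join key across the pipeline). Defaults to `rownames(counts)`.
#' @param cell_ids Character vector of cell identifiers. Defaults to
#'   `colnames(counts)`.
#' @param cell_groups Optional named character vector mapping cell id to a
#'   group label such as `"CTC"` or `"control"`.
#'
#' @return An object of class `ctc_counts`: a list with elements `counts`
#'   (dense matrix with dimnames), `gene_ids`, `cell_ids`, `cell_groups`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), cell_groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids)) {
    stop(sprintf("matrix has %d rows but %d gene ids were supplied",
                 nrow(counts), length(gene_ids)))
  }
  if (ncol(counts) != length(cell_ids)) {
    stop(sprintf("matrix has %d columns but %d cell ids were supplied",
                 ncol(counts), length(cell_ids)))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (!is.null(cell_groups)) {
    if (is.null(names(cell_groups)) || !all(names(cell_groups) %in% cell_ids)) {
      stop("cell_groups must be named by cell id")
    }
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_groups = cell_groups),
            class = "ctc_counts")
}

#' @export
print.ctc_counts <- function(x, ...) {
  cat(sprintf("ctc_counts: %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  if (!is.null(x$cell_groups)) {
    tab <- table(x$cell_groups)
    cat("cell groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a count matrix by gene and/or cell identifiers
#'
#' @param x A `ctc_counts` object.
#' @param genes,cells Character vectors of identifiers to retain (default all).
#' @return A `ctc_counts` object.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ctc_counts"))
  genes <- if (is.null(genes)) x$gene_ids else genes
  cells <- if (is.null(cells)) x$cell_ids else cells
  missing_g <- setdiff(genes, x$gene_ids)
  missing_c <- setdiff(cells, x$cell_ids)
  if (length(missing_g)) stop("unknown gene id(s): ", paste(utils::head(missing_g, 5), collapse = ", "))
  if (length(missing_c)) stop("unknown cell id(s): ", paste(utils::head(missing_c, 5), collapse = ", "))
  grp <- x$cell_groups
  if (!is.null(grp)) grp <- grp[names(grp) %in% cells]
  count_matrix(x$counts[genes, cells, drop = FALSE], genes, cells, grp)
}

#' Read a count matrix from Matrix Market or dense TSV
#'
#' Matrix Market files use the single-cell exchange convention: 1-based triplet
#' indices, genes as rows, cells as columns. Entries absent from a triplet file
#' are zero. A file that does not start with the `%%MatrixMarket` banner is
#' read as a dense numeric TSV (genes as rows, no header).
#'
#' @param matrix_path Path to the `.mtx` or dense TSV file.
#' @param gene_path,cell_path Label files, one identifier per line.
#' @param cell_groups Optional named group vector, see [count_matrix()].
#' @return A `ctc_counts` object.
#' @export
read_count_matrix <- function(matrix_path, gene_path, cell_path,
                              cell_groups = NULL) {
  gene_ids <- readLines(gene_path)
  cell_ids <- readLines(cell_path)
  first <- readLines(matrix_path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    m <- as.matrix(Matrix::readMM(matrix_path))
  } else {
    m <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t",
                                     colClasses = "numeric"))
  }
  if (nrow(m) != length(gene_ids)) {
    stop(sprintf("matrix declares %d rows but gene file has %d ids",
                 nrow(m), length(gene_ids)))
  }
  if (ncol(m) != length(cell_ids)) {
    stop(sprintf("matrix declares %d columns but cell file has %d ids",
                 ncol(m), length(cell_ids)))
  }
  count_matrix(m, gene_ids, cell_ids, cell_groups)
}

#' Write a count matrix as Matrix Market plus label files
#'
#' @param x A `ctc_counts` object.
#' @param matrix_path,gene_path,cell_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, matrix_path, gene_path, cell_path) {
  stopifnot(inherits(x, "ctc_counts"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), matrix_path)
  writeLines(x$gene_ids, gene_path)
  writeLines(x$cell_ids, cell_path)
  invisible(x)
}

# Strict numeric parse: unparseable fields fail loudly rather than coerce to 0,
# which would silently move filter boundaries.
parse_numeric_strict <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x) & nzchar(trimws(x))
  if (any(bad) || anyNA(x)) {
    stop(sprintf("non-numeric value in %s: '%s'", what,
                 as.character(x[bad | is.na(x)][1])))
  }
  out
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `symbol`, `biotype`, `locations`;
#' `locations` is a semicolon-separated list of subcellular locations (e.g.
#' `plasma_membrane;cytosol`), empty meaning no annotated location.
#'
#' @param path Path to the TSV file.
#' @return A `gene_annotation` object: data frame with columns `gene_id`,
#'   `symbol`, `biotype` and list-column `locations` (character vectors).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  need <- c("gene_id", "symbol", "biotype", "locations")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  gene_annotation(df$gene_id, df$symbol, df$biotype,
                  strsplit(df$locations, ";", fixed = TRUE))
}

#' Construct a gene annotation table in memory
#'
#' @param gene_id,symbol,biotype Character vectors, one entry per gene.
#' @param locations List of character vectors (subcellular locations per gene).
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, biotype, locations) {
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in annotation: ",
         gene_id[duplicated(gene_id)][1])
  }
  if (any(!nzchar(biotype))) stop("biotype must be non-empty for every gene")
  locations <- lapply(locations, function(l) {
    l <- l[nzchar(l)]
    if (!length(l)) character(0) else unique(l)
  })
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  out$locations <- locations
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Look up annotation records for a set of genes
#'
#' Genes absent from the annotation come back with `biotype = NA` and an empty
#' location set; the cascade's biotype/location filters treat them as failing
#' (unknown is not evidence of a protein-coding surface gene).
#'
#' @param ann A `gene_annotation` object.
#' @param genes Character vector of gene ids.
#' @param ignore_case Match identifiers case-insensitively (default exact).
#' @return Data frame aligned to `genes` with columns `gene_id`, `biotype` and
#'   list-column `locations`.
#' @export
annotation_lookup <- function(ann, genes, ignore_case = FALSE) {
  stopifnot(inherits(ann, "gene_annotation"))
  key <- if (ignore_case) toupper(ann$gene_id) else ann$gene_id
  qry <- if (ignore_case) toupper(genes) else genes
  idx <- match(qry, key)
  out <- data.frame(gene_id = genes,
                    biotype = ifelse(is.na(idx), NA_character_, ann$biotype[idx]),
                    stringsAsFactors = FALSE)
  out$locations <- lapply(idx, function(i) {
    if (is.na(i)) character(0) else ann$locations[[i]]
  })
  out
}

#' Construct a blood-expression reference
#'
#' Per-gene evidence that a gene is expressed in blood: the maximum single-cell
#' count observed across PBMC cell types, and whole-blood expression in
#' TPM-like units. A gene missing from the reference is treated as (0, 0) —
#' absence of evidence of blood expression.
#'
#' @param gene_id Character vector.
#' @param pbmc_max_count,blood_expression Non-negative numeric vectors.
#' @return A `blood_reference` data frame.
#' @export
blood_reference <- function(gene_id, pbmc_max_count, blood_expression) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in blood reference")
  if (any(pbmc_max_count < 0) || any(blood_expression < 0)) {
    stop("blood reference values must be non-negative")
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    pbmc_max_count = as.numeric(pbmc_max_count),
                    blood_expression = as.numeric(blood_expression),
                    stringsAsFactors = FALSE)
  class(out) <- c("blood_reference", "data.frame")
  out
}

#' Read and merge the two blood-reference tables
#'
#' @param pbmc_path TSV with header columns `gene_id`, `pbmc_max_count`.
#' @param blood_path TSV with header columns `gene_id`, `blood_expression`.
#' @return A `blood_reference` object; genes present in only one table get 0
#'   for the other field.
#' @export
read_blood_reference <- function(pbmc_path, blood_path) {
  pb <- utils::read.table(pbmc_path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  bl <- utils::read.table(blood_path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("gene_id", "pbmc_max_count") %in% names(pb))) {
    stop("PBMC table must have columns gene_id, pbmc_max_count")
  }
  if (!all(c("gene_id", "blood_expression") %in% names(bl))) {
    stop("blood table must have columns gene_id, blood_expression")
  }
  pbv <- parse_numeric_strict(pb$pbmc_max_count, "pbmc_max_count")
  blv <- parse_numeric_strict(bl$blood_expression, "blood_expression")
  ids <- union(pb$gene_id, bl$gene_id)
  blood_reference(
    ids,
    pbmc_max_count = ifelse(is.na(match(ids, pb$gene_id)), 0,
                            pbv[match(ids, pb$gene_id)]),
    blood_expression = ifelse(is.na(match(ids, bl$gene_id)), 0,
                              blv[match(ids, bl$gene_id)])
  )
}

#' Query blood-reference values for a set of genes
#'
#' Missing genes always return `(0, 0)`, never an error.
#'
#' @inheritParams annotation_lookup
#' @param ref A `blood_reference` object.
#' @return Data frame aligned to `genes` with `pbmc_max_count` and
#'   `blood_expression`.
#' @export
blood_lookup <- function(ref, genes, ignore_case = FALSE) {
  stopifnot(inherits(ref, "blood_reference"))
  key <- if (ignore_case) toupper(ref$gene_id) else ref$gene_id
  qry <- if (ignore_case) toupper(genes) else genes
  idx <- match(qry, key)
  data.frame(gene_id = genes,
             pbmc_max_count = ifelse(is.na(idx), 0, ref$pbmc_max_count[idx]),
             blood_expression = ifelse(is.na(idx), 0, ref$blood_expression[idx]),
             stringsAsFactors = FALSE)
}

#' Read a per-cell alignment-statistics table
#'
#' @param path TSV with header columns `cell_id`, `unique_map_pct` and
#'   optionally `total_reads`.
#' @return Data frame with those columns; `unique_map_pct` validated to
#'   lie in \[0, 100\].
#' @export
read_alignment_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("cell_id", "unique_map_pct") %in% names(df))) {
    stop("alignment stats must have columns cell_id, unique_map_pct")
  }
  out <- data.frame(cell_id = df$cell_id,
                    unique_map_pct = parse_numeric_strict(df$unique_map_pct,
                                                          "unique_map_pct"),
                    stringsAsFactors = FALSE)
  if ("total_reads" %in% names(df)) {
    out$total_reads <- parse_numeric_strict(df$total_reads, "total_reads")
  }
  if (any(out$unique_map_pct < 0 | out$unique_map_pct > 100)) {
    stop("unique_map_pct must lie in [0, 100]")
  }
  out
}

#' Write a machine-readable screen report
#'
#' Serializes a completed cascade result plus a QC summary to JSON. The report
#' preserves stage order, per-stage gene lists and the threshold configuration,
#' so reading it back reproduces the result exactly.
#'
#' @param cascade_result A `cascade_result` object, see [run_cascade()].
#' @param qc_summary Any JSON-serializable list of QC facts (may be `NULL`).
#' @param path Output path.
#' @return Invisibly, the report list that was written.
#' @export
write_screen_report <- function(cascade_result, qc_summary = NULL, path) {
  stopifnot(inherits(cascade_result, "cascade_result"))
  report <- list(
    schema = "ctcscreen/screen-report/1",
    stages = lapply(cascade_result$stages, function(s) {
      list(name = s$name, n_in = s$n_in, n_out = s$n_out, genes = I(s$genes))
    }),
    candidates = cascade_result$candidates,
    config = cascade_result$config,
    qc_summary = qc_summary
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

#' Read back a screen report written by [write_screen_report()]
#'
#' @param path Path to the JSON report.
#' @return A list with `stages` (name, n_in, n_out, genes), `candidates`,
#'   `config`, `qc_summary`.
#' @export
read_screen_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  rep$stages <- lapply(rep$stages, function(s) {
    s$genes <- as.character(unlist(s$genes))
    s$n_in <- as.integer(s$n_in)
    s$n_out <- as.integer(s$n_out)
    s
  })
  rep
}
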