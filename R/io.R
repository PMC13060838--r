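#' Read genomic intervals from BED or header-carrying TSV
#'
#' Internal coordinates are uniformly 0-based half-open; 1-based inclusive
#' (GTF-like) inputs are converted at the boundary. Records are sorted by
#' (chrom, start) after loading. Gzipped files are read transparently.
#'
#' @param path file path.
#' @param format "bed" (headerless chrom/start/end/name/score/strand) or
#'   "tsv" (header must include chrom, start, end).
#' @param coords coordinate convention of the file on disk: "base0" (0-based
#'   half-open, the default for BED) or "base1" (1-based inclusive, GTF-like).
#' @return data.frame with columns chrom, start, end and any extra columns,
#'   sorted by (chrom, start).
#' @export
read_intervals <- function(path, format = c("bed", "tsv"), coords = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  if (is.null(coords)) coords <- if (format == "bed") "base0" else "base0"
  if (!coords %in% c("base0", "base1")) stop_config("coords must be 'base0' or 'base1'")
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop_parse("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3)[1], path)
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
      end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3))),
      stringsAsFactors = FALSE)
    if (max(nf) >= 4) df$name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
    if (max(nf) >= 5) df$score <- suppressWarnings(as.numeric(
      vapply(parts, function(p) if (length(p) >= 5) p[5] else NA_character_, "")))
    if (max(nf) >= 6) df$strand <- vapply(parts, function(p) if (length(p) >= 6) p[6] else NA_character_, "")
    bad <- which(!is.finite(df$start) | !is.finite(df$end))
    if (length(bad)) stop_parse("malformed BED line %d in %s: non-numeric coordinate",
                                bad[1], path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop_parse("TSV %s lacks required column(s): %s",
                                 path, paste(miss, collapse = ", "))
  }
  if (coords == "base1") {
    df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  }
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop_integrity("interval with start >= end at record %d of %s", bad[1], path)
  if (any(df$start < 0)) stop_integrity("negative start coordinate in %s", path)
  df$start <- as.integer(round(df$start)); df$end <- as.integer(round(df$end))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals to BED or TSV (0-based half-open)
#'
#' @param df data.frame with chrom, start, end (+ optional name/score/strand
#'   and other columns for TSV).
#' @param path destination file.
#' @param format "bed" or "tsv".
#' @export
write_intervals <- function(df, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
    utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a labeled sparse count matrix (MatrixMarket + label files)
#'
#' @param mtx_path MatrixMarket file (genes x cells).
#' @param genes_path one gene id per line.
#' @param barcodes_path one cell barcode per line.
#' @return dgCMatrix with dimnames attached.
#' @export
read_count_matrix <- function(mtx_path, genes_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  cells <- readLines(barcodes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop_integrity("MTX dimensions (%d x %d) do not match label files (%d genes, %d barcodes)",
                   nrow(m), ncol(m), length(genes), length(cells))
  if (length(m@x) && any(m@x != round(m@x)))
    stop_integrity("count matrix has non-integer entries")
  dimnames(m) <- list(genes, cells)
  m
}

#' @rdname read_count_matrix
#' @param m labeled sparse matrix to write.
#' @param dir output directory; writes matrix.mtx, genes.tsv, barcodes.tsv.
#' @export
write_count_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_dependency("required input missing: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a full synthetic fixture set
#'
#' Persists the annotation, ground truth and screen dataset as the plain-text
#' formats the pipeline consumes (MTX + labels, TSV tables, BED intervals),
#' so that synthetic and user-supplied real data enter identically.
#'
#' @param annotation a [genome_annotation()].
#' @param truth a `regulatory_truth`.
#' @param dir output directory.
#' @export
write_truth <- function(annotation, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(annotation), file.path(dir, "annotation.tsv"))
  cre_bed <- data.frame(chrom = truth$cres$chrom, start = truth$cres$start,
                        end = truth$cres$end, name = truth$cres$cre_id)
  write_intervals(cre_bed, file.path(dir, "cres.bed"), "bed")
  write_tsv(truth$cres, file.path(dir, "cre_annot.tsv"))
  write_tsv(truth$links, file.path(dir, "truth_links.tsv"))
  write_tsv(truth$trans_edges, file.path(dir, "trans_edges.tsv"))
  write_intervals(truth$tads, file.path(dir, "tads.bed"), "bed")
  write_tsv(truth$hic, file.path(dir, "hic.tsv"))
  write_tsv(truth$panels, file.path(dir, "panels.tsv"))
  for (nm in names(truth$prediction_sources))
    write_tsv(truth$prediction_sources[[nm]],
              file.path(dir, sprintf("predictions_%s.tsv", nm)))
  for (nm in names(truth$eqtl_catalogs))
    write_tsv(truth$eqtl_catalogs[[nm]],
              file.path(dir, sprintf("eqtl_%s.tsv", nm)))
  writeLines(truth$diseases, file.path(dir, "diseases.txt"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  ann <- genome_annotation(read_tsv(file.path(dir, "annotation.tsv")))
  cres <- read_tsv(file.path(dir, "cre_annot.tsv"))
  pred_files <- list.files(dir, "^predictions_.*\\.tsv$", full.names = TRUE)
  eqtl_files <- list.files(dir, "^eqtl_.*\\.tsv$", full.names = TRUE)
  named_read <- function(files, prefix) {
    out <- lapply(files, read_tsv)
    names(out) <- sub("\\.tsv$", "", sub(paste0("^", prefix), "", basename(files)))
    out
  }
  truth <- structure(list(
    cres = cres,
    links = read_tsv(file.path(dir, "truth_links.tsv")),
    trans_edges = read_tsv(file.path(dir, "trans_edges.tsv")),
    tads = {
      t <- read_intervals(file.path(dir, "tads.bed"), "bed")
      names(t)[names(t) == "name"] <- "name"; t
    },
    hic = read_tsv(file.path(dir, "hic.tsv")),
    panels = read_tsv(file.path(dir, "panels.tsv")),
    prediction_sources = named_read(pred_files, "predictions_"),
    eqtl_catalogs = named_read(eqtl_files, "eqtl_"),
    diseases = readLines(file.path(dir, "diseases.txt")),
    params = NULL
  ), class = "regulatory_truth")
  list(annotation = ann, truth = truth)
}

#' @rdname write_truth
#' @param dataset a `screen_dataset`.
#' @export
write_screen_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(dataset$counts, dir)
  write_tsv(dataset$cells, file.path(dir, "cells.tsv"))
  write_tsv(dataset$assignments, file.path(dir, "assignments.tsv"))
  write_tsv(dataset$grna_table, file.path(dir, "grnas.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_screen_dataset <- function(dir) {
  counts <- read_count_matrix(file.path(dir, "matrix.mtx"),
                              file.path(dir, "genes.tsv"),
                              file.path(dir, "barcodes.tsv"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  if (!identical(cells$cell_id, colnames(counts)))
    stop_integrity("cells.tsv does not match matrix barcodes in %s", dir)
  assignments <- read_tsv(file.path(dir, "assignments.tsv"))
  bad <- setdiff(assignments$cell_id, cells$cell_id)
  if (length(bad))
    stop_integrity("assignments reference unknown cell(s), e.g. %s", bad[1])
  structure(list(counts = counts, cells = cells, assignments = assignments,
                 grna_table = read_tsv(file.path(dir, "grnas.tsv")),
                 config = NULL),
            class = "screen_dataset")
}
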