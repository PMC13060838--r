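#' Construct and validate a genome annotation table
#'
#' The annotation is the coordinate frame for every classification step.
#' One row per gene with its transcription start site (TSS), strand, gene
#' body interval (0-based, half-open), an expected UMI-per-cell baseline and
#' a negative-binomial dispersion.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end`, `baseline_mean`, `dispersion`.
#' @return A validated `genome_annotation` (a data.frame).
#' @export
genome_annotation <- function(df) {
  req <- c("gene_id", "chrom", "tss", "strand", "body_start", "body_end",
           "baseline_mean", "dispersion")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_integrity("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop_integrity("gene_ids are not unique")
  if (!all(df$strand %in% c("+", "-")))
    stop_integrity("strand must be '+' or '-'")
  if (any(df$body_start >= df$body_end))
    stop_integrity("body_start must be < body_end for every gene")
  if (any(df$tss < df$body_start | df$tss >= df$body_end))
    stop_integrity("tss must lie within the gene body interval")
  if (any(df$baseline_mean < 0)) stop_integrity("baseline_mean must be nonnegative")
  if (any(df$dispersion <= 0)) stop_integrity("dispersion must be positive")
  df <- as.data.frame(df)[req]
  df <- df[order(df$chrom, df$tss), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Infer a TSS when one is not given explicitly
#'
#' On the + strand the TSS is the body start; on the - strand it is the last
#' base of the body (`body_end - 1` in 0-based half-open coordinates).
#'
#' @param body_start,body_end integer vectors (0-based half-open).
#' @param strand character vector of "+"/"-".
#' @return integer vector of TSS positions.
#' @export
infer_tss <- function(body_start, body_end, strand) {
  ifelse(strand == "+", body_start, body_end - 1L)
}

#' Unsigned distance from CRE centers to gene TSSs
#'
#' Distance is measured from the integer midpoint of each CRE interval to
#' the TSS of the paired gene; it is unsigned and strand-free.
#'
#' @param cre_start,cre_end CRE interval (0-based half-open), vectorized.
#' @param tss TSS positions, same length.
#' @return numeric vector of distances in bp.
#' @export
cre_tss_distance <- function(cre_start, cre_end, tss) {
  abs(floor((cre_start + cre_end) / 2) - tss)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more genes\n", nrow(x) - 6L))
  invisible(x)
}
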