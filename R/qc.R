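#' Filter cells and resolve unique gRNA assignments
#'
#' Retains cells passing UMI and detected-gene thresholds that carry exactly
#' one assigned gRNA, then drops gRNAs observed in fewer than
#' `min_cells_per_grna` surviving cells (together with their cells).
#'
#' @param dataset a `screen_dataset`.
#' @param min_umi minimum total UMI per cell.
#' @param min_genes minimum detected genes per cell.
#' @param min_cells_per_grna minimum surviving cells per gRNA (default 10).
#' @return filtered `screen_dataset`; `$qc_summary` reports the fraction of
#'   input cells uniquely assigned and retained.
#' @export
filter_and_assign <- function(dataset, min_umi = 100, min_genes = 10,
                              min_cells_per_grna = 10) {
  counts <- dataset$counts
  umi <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  pass_qc <- umi >= min_umi & ngene >= min_genes

  tab <- table(dataset$assignments$cell_id)
  unique_cells <- names(tab)[tab == 1]
  keep <- dataset$cells$cell_id[pass_qc]
  keep <- intersect(keep, unique_cells)

  asn <- dataset$assignments[dataset$assignments$cell_id %in% keep, , drop = FALSE]
  gtab <- table(asn$grna_id)
  good_grnas <- names(gtab)[gtab >= min_cells_per_grna]
  asn <- asn[asn$grna_id %in% good_grnas, , drop = FALSE]
  keep <- asn$cell_id

  if (!length(keep)) stop_integrity("no cells survive QC")

  ord <- match(keep, dataset$cells$cell_id)
  out <- dataset
  out$counts <- counts[, ord, drop = FALSE]
  out$cells <- dataset$cells[ord, , drop = FALSE]
  rownames(out$cells) <- NULL
  out$assignments <- asn
  out$grna_table <- dataset$grna_table[dataset$grna_table$grna_id %in% good_grnas, ,
                                       drop = FALSE]
  out$qc_summary <- list(
    n_input_cells = ncol(counts),
    n_retained_cells = length(keep),
    fraction_uniquely_assigned = length(unique_cells) / ncol(counts),
    fraction_retained = length(keep) / ncol(counts),
    n_grnas_dropped = sum(gtab < min_cells_per_grna))
  out
}

.lognorm_expr <- function(counts, gene, cells_idx, lib, scale) {
  log1p(counts[gene, cells_idx] / lib[cells_idx] * scale)
}

#' Per-gRNA on-target knockdown efficiency
#'
#' Contrasts the mean log-normalized expression (log1p of counts scaled to a
#' fixed library size) of each gRNA's target gene between cells carrying that
#' gRNA and non-targeting control cells. Significance is a two-sided Wilcoxon
#' rank-sum test per gRNA, BH-corrected across gRNAs.
#'
#' @param dataset filtered `screen_dataset` (see [filter_and_assign()]).
#' @param target_gene_of named character vector mapping target_id to the gene
#'   it knocks down (promoter targets); targets absent from it are skipped.
#' @param normalization_scale per-cell library scaling constant (default 1e4).
#' @param min_cells minimum cells per gRNA to test.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of `KnockdownRecord`s, one row per tested gRNA.
#' @export
knockdown_table <- function(dataset, target_gene_of, normalization_scale = 1e4,
                            min_cells = 10, alpha = 0.05) {
  counts <- dataset$counts
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  cell_of <- split(dataset$assignments$cell_id, dataset$assignments$grna_id)
  grnas <- dataset$grna_table
  nt_ids <- grnas$grna_id[grnas$target_type == "non-targeting"]
  nt_cells <- match(unlist(cell_of[nt_ids], use.names = FALSE), colnames(counts))
  if (!length(nt_cells)) stop_integrity("non-targeting control pool is empty")

  test <- grnas[grnas$target_id %in% names(target_gene_of), , drop = FALSE]
  res <- lapply(seq_len(nrow(test)), function(i) {
    gid <- test$grna_id[i]
    gene <- target_gene_of[[test$target_id[i]]]
    if (!gene %in% rownames(counts))
      stop_integrity("target gene '%s' absent from count matrix", gene)
    idx <- match(cell_of[[gid]], colnames(counts))
    idx <- idx[!is.na(idx)]
    if (length(idx) < min_cells) return(NULL)
    xp <- .lognorm_expr(counts, gene, idx, lib, normalization_scale)
    xc <- .lognorm_expr(counts, gene, nt_cells, lib, normalization_scale)
    p <- tryCatch(suppressWarnings(stats::wilcox.test(xp, xc)$p.value),
                  error = function(e) NA_real_)
    data.frame(grna_id = gid, target_gene = gene, n_cells = length(idx),
               mean_lognorm_perturbed = mean(xp), mean_lognorm_control = mean(xc),
               kd_ratio = if (mean(xc) > 0) mean(xp) / mean(xc) else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) stop_integrity("no gRNA passed the cell threshold")
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' @rdname knockdown_table
#' @param grna_id single gRNA to quantify (significance from the full table).
#' @export
knockdown_efficiency <- function(dataset, grna_id, target_gene_of,
                                 normalization_scale = 1e4, min_cells = 10,
                                 alpha = 0.05) {
  tab <- knockdown_table(dataset, target_gene_of, normalization_scale,
                         min_cells, alpha)
  rec <- tab[tab$grna_id == grna_id, , drop = FALSE]
  if (!nrow(rec)) stop_integrity("gRNA '%s' was not tested", grna_id)
  rec
}
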