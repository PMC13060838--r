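# half-open [s, e) intervals -> GRanges (1-based closed)
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Genomic context of CREs
#'
#' A CRE is `promoter` when its interval overlaps any TSS +/- proximal
#' window, else `intragenic` when its center lies inside any gene body,
#' else `intergenic`. All coordinates are 0-based half-open.
#'
#' @param cres data.frame with cre_id, chrom, start, end.
#' @param annotation a [genome_annotation()].
#' @param proximal_window half-width of the promoter window in bp
#'   (default 1500).
#' @return character vector of contexts, one per CRE.
#' @export
classify_cre_context <- function(cres, annotation, proximal_window = 1500) {
  w <- proximal_window
  cre_gr <- .gr(cres$chrom, cres$start, cres$end)
  tss_gr <- .gr(annotation$chrom, pmax(annotation$tss - w, 0), annotation$tss + w)
  is_prom <- GenomicRanges::countOverlaps(cre_gr, tss_gr) > 0
  center <- floor((cres$start + cres$end) / 2)
  cen_gr <- .gr(cres$chrom, center, center + 1)
  body_gr <- .gr(annotation$chrom, annotation$body_start, annotation$body_end)
  in_body <- GenomicRanges::countOverlaps(cen_gr, body_gr) > 0
  ifelse(is_prom, "promoter", ifelse(in_body, "intragenic", "intergenic"))
}

#' Interaction class of a CRE-gene link
#'
#' Combines CRE genomic context with target proximity: `proximal` when the
#' CRE-center-to-TSS distance is below the proximal window, else `distal`.
#' Intergenic CREs are distal by construction (any CRE within the window of
#' a TSS is promoter-context), giving the five classes promoter-proximal,
#' promoter-distal, intragenic-proximal, intragenic-distal and
#' intergenic-distal.
#'
#' @param cre_context character vector of contexts.
#' @param distance CRE-center-to-target-TSS distances in bp.
#' @param proximal_window proximity threshold in bp (default 1500).
#' @return character vector of interaction classes.
#' @export
classify_interaction <- function(cre_context, distance, proximal_window = 1500) {
  position <- ifelse(distance < proximal_window, "proximal", "distal")
  position[cre_context == "intergenic"] <- "distal"
  paste(cre_context, position, sep = "-")
}

#' Call cis-regulatory CRE-gene links from CRE-screen DE results
#'
#' Thresholds DE results (adjusted p below `fdr` and |log2FC| at least
#' `min_abs_lfc`), annotates genomic context, distance and interaction
#' class, and excludes associations from control promoter perturbations and
#' across chromosomes from the cis set while retaining them in an audit
#' table.
#'
#' @param de_results `de_result` table in CRE mode (perturbation = cre_id).
#' @param cre_table data.frame with cre_id, chrom, start, end.
#' @param annotation a [genome_annotation()].
#' @param control_promoter_ids perturbation ids that are positive-control
#'   promoters, excluded from the cis set.
#' @param fdr BH-adjusted significance threshold (default 0.1).
#' @param min_abs_lfc |log2FC| gate at link calling (default 0).
#' @param proximal_window bp (default 1500).
#' @param prediction_sources optional named list of data.frames
#'   (cre_id, gene_id) used to annotate each link's supporting sources.
#' @return list with `links` (all tested same-chromosome non-control pairs,
#'   class `cre_gene_links`), `audit` (significant excluded associations
#'   with a reason), and `summary` (degree statistics of the cis set).
#' @export
call_links <- function(de_results, cre_table, annotation,
                       control_promoter_ids = character(), fdr = 0.1,
                       min_abs_lfc = 0, proximal_window = 1500,
                       prediction_sources = NULL) {
  d <- as.data.frame(de_results)
  is_ctrl <- d$perturbation %in% control_promoter_ids
  missing_cre <- setdiff(unique(d$perturbation[!is_ctrl]), cre_table$cre_id)
  if (length(missing_cre))
    stop_integrity("perturbation(s) absent from cre_table: %s",
                   paste(utils::head(missing_cre, 3), collapse = ", "))

  ci <- match(d$perturbation, cre_table$cre_id)
  gi <- match(d$response_gene, annotation$gene_id)
  if (anyNA(gi)) stop_integrity("DE response gene absent from annotation")

  d$cre_id <- d$perturbation
  d$gene_id <- d$response_gene
  d$significant <- !is.na(d$adj_p) & d$adj_p < fdr & abs(d$log2fc) >= min_abs_lfc
  d$same_chromosome <- !is_ctrl & cre_table$chrom[ci] == annotation$chrom[gi]
  d$distance <- ifelse(d$same_chromosome,
                       cre_tss_distance(cre_table$start[ci], cre_table$end[ci],
                                        annotation$tss[gi]),
                       NA_real_)
  ctx <- rep(NA_character_, nrow(d))
  ok <- which(!is_ctrl)
  if (length(ok)) {
    ctx_by_cre <- classify_cre_context(cre_table, annotation, proximal_window)
    ctx[ok] <- ctx_by_cre[ci[ok]]
  }
  d$cre_context <- ctx
  d$position <- ifelse(!is.na(d$distance) & d$distance < proximal_window,
                       "proximal", "distal")
  d$position[d$cre_context == "intergenic"] <- "distal"
  d$interaction_class <- ifelse(d$same_chromosome & !is.na(d$cre_context),
                                classify_interaction(d$cre_context, d$distance,
                                                     proximal_window),
                                NA_character_)
  d$direction <- ifelse(d$log2fc < 0, "down", "up")

  if (!is.null(prediction_sources)) {
    key <- paste(d$cre_id, d$gene_id)
    src <- vapply(key, function(k) "", "")
    for (nm in names(prediction_sources)) {
      ps <- prediction_sources[[nm]]
      hit <- key %in% paste(ps$cre_id, ps$gene_id)
      src[hit] <- ifelse(nzchar(src[hit]), paste(src[hit], nm, sep = ","), nm)
    }
    d$prediction_sources <- unname(src)
  }

  sig <- d$significant
  with_reason <- function(df, reason) {
    df$reason <- rep_len(reason, nrow(df))
    df
  }
  audit <- rbind(
    with_reason(d[sig & is_ctrl, , drop = FALSE], "control_promoter"),
    with_reason(d[sig & !is_ctrl & !d$same_chromosome, , drop = FALSE],
                "cross_chromosome"))
  links <- d[!is_ctrl & d$same_chromosome, , drop = FALSE]
  rownames(links) <- rownames(audit) <- NULL
  class(links) <- c("cre_gene_links", "data.frame")

  cis <- links[links$significant, , drop = FALSE]
  per_cre <- if (nrow(cis)) table(cis$cre_id) else integer(0)
  per_gene <- if (nrow(cis)) table(cis$gene_id) else integer(0)
  summary <- list(
    n_cis_links = nrow(cis),
    n_excluded_control = sum(sig & is_ctrl),
    n_excluded_cross_chromosome = sum(sig & !is_ctrl & !d$same_chromosome),
    mean_targets_per_cre = if (length(per_cre)) mean(per_cre) else NA_real_,
    mean_cres_per_gene = if (length(per_gene)) mean(per_gene) else NA_real_,
    fraction_upregulated = if (nrow(cis)) mean(cis$log2fc > 0) else NA_real_,
    fraction_downregulated = if (nrow(cis)) mean(cis$log2fc < 0) else NA_real_)
  list(links = links, audit = audit, summary = summary)
}

#' Benchmark CRE-gene prediction sources against screen validation
#'
#' For each source: the number of tested pairs it predicted, how many of
#' those were significant in the screen ("validated"), the precision, and
#' the fraction of validated predictions that are distal. Two pooled rows
#' report pairs predicted by any source and by none; the fold enrichment is
#' precision(any) / precision(none).
#'
#' @param links `cre_gene_links` table (tested pairs with `significant`).
#' @param prediction_sources named list of data.frames (cre_id, gene_id).
#' @param targeted_sources sources counted as in-silico predictions for the
#'   pooled `any_source` / `no_source` comparison (default: all; pass the
#'   regulatory-evidence sources to contrast them with distance-only pairs).
#' @return data.frame, one row per source plus `any_source` / `no_source`;
#'   attribute `fold_vs_unpredicted` carries the fold enrichment.
#' @export
benchmark_predictions <- function(links, prediction_sources,
                                  targeted_sources = names(prediction_sources)) {
  key <- paste(links$cre_id, links$gene_id)
  pred_mat <- vapply(prediction_sources, function(ps)
    key %in% paste(ps$cre_id, ps$gene_id), logical(length(key)))
  if (is.null(dim(pred_mat))) pred_mat <- matrix(pred_mat, nrow = length(key),
                                                 dimnames = list(NULL, names(prediction_sources)))
  tcol <- intersect(targeted_sources, colnames(pred_mat))
  any_pred <- rowSums(pred_mat[, tcol, drop = FALSE]) > 0

  row_for <- function(name, mask) {
    n_pred <- sum(mask)
    n_val <- sum(mask & links$significant)
    distal <- if (n_val)
      mean(links$position[mask & links$significant] == "distal") else NA_real_
    data.frame(source = name, n_predicted = n_pred, n_validated = n_val,
               precision = if (n_pred) n_val / n_pred else NA_real_,
               distal_fraction_validated = distal, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(
    lapply(seq_along(prediction_sources), function(j)
      row_for(names(prediction_sources)[j], pred_mat[, j])),
    list(row_for("any_source", any_pred), row_for("no_source", !any_pred))))
  p_any <- res$precision[res$source == "any_source"]
  p_none <- res$precision[res$source == "no_source"]
  attr(res, "fold_vs_unpredicted") <-
    if (!is.na(p_any) && !is.na(p_none) && p_none > 0) p_any / p_none else NA_real_
  res
}
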