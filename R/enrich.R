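#' Fisher's exact test with cross-ratio odds ratio
#'
#' The p-value is the exact conditional two-sided (or one-sided) probability
#' from the hypergeometric distribution on the uncorrected table. The odds
#' ratio is the sample cross-ratio a*d / (b*c); when any cell is zero a
#' Haldane-Anscombe +0.5 correction is applied to every cell and flagged.
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#'   (rows: condition, cols: outcome).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list(odds_ratio, log_or, p, corrected).
#' @export
fisher_or <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop_config("fisher_or requires a 2x2 table of nonnegative integers")
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, log_or = log(or), p = p, corrected = corrected)
}

.enrichment_row <- function(name, a, b, c, d, alternative = "two.sided") {
  fr <- fisher_or(matrix(c(a, c, b, d), 2), alternative)
  data.frame(name = name, a = a, b = b, c = c, d = d,
             odds_ratio = fr$odds_ratio, log_or = fr$log_or, p = fr$p,
             corrected = fr$corrected, n_overlap = a, stringsAsFactors = FALSE)
}

#' eQTL support enrichment among significant CRE-gene links
#'
#' Per catalog: the 2x2 table {significant, non-significant} x
#' {eQTL-supported, not} over the prioritized universe of tested pairs
#' (by default those predicted by at least one source; pass
#' `universe = NULL` to use all tested pairs).
#'
#' @param links tested-pair table with cre_id, gene_id, significant (and a
#'   `prediction_sources` column when the default universe is used).
#' @param eqtl_catalogs named list of data.frames (cre_id, gene_id).
#' @param universe "predicted" (default) restricts to pairs predicted by at
#'   least one source; NULL uses all tested pairs.
#' @return data.frame of `EnrichmentResult` rows, one per catalog, plus a
#'   per-class overlap breakdown in the attribute `class_breakdown`.
#' @export
eqtl_enrichment <- function(links, eqtl_catalogs, universe = "predicted") {
  u <- as.data.frame(links)
  if (identical(universe, "predicted") && "prediction_sources" %in% names(u))
    u <- u[nzchar(u$prediction_sources), , drop = FALSE]
  key <- paste(u$cre_id, u$gene_id)
  res <- do.call(rbind, lapply(names(eqtl_catalogs), function(nm) {
    cat_key <- paste(eqtl_catalogs[[nm]]$cre_id, eqtl_catalogs[[nm]]$gene_id)
    supp <- key %in% cat_key
    .enrichment_row(nm,
                    a = sum(u$significant & supp),
                    b = sum(u$significant & !supp),
                    c = sum(!u$significant & supp),
                    d = sum(!u$significant & !supp))
  }))
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  if ("interaction_class" %in% names(u)) {
    all_keys <- unique(unlist(lapply(eqtl_catalogs, function(cc)
      paste(cc$cre_id, cc$gene_id))))
    supp_any <- key %in% all_keys
    sig <- u$significant
    attr(res, "class_breakdown") <- as.data.frame(
      table(interaction_class = u$interaction_class[sig],
            eqtl_supported = supp_any[sig]))
  }
  res
}

#' Transcription-factor target enrichment among a perturbation's DEGs
#'
#' For each perturbed TF with at least `min_targets` annotated targets and
#' `min_degs` DEGs (at `deg_adj_p`, `deg_min_abs_lfc`): a one-sided Fisher
#' test of its DEGs against its target set over the tested response
#' universe, plus a concordant/discordant/unsigned split comparing the DEG
#' sign to the annotated regulatory direction (knocking down a TF should
#' lower its activating targets and raise its repressed ones).
#'
#' @param de_results promoter-screen `de_result` table; perturbation labels
#'   must equal TF names (any "P_" prefix is stripped).
#' @param tf_target_sets named list per TF of data.frames with `target` and
#'   optional `mor` (+1 activating / -1 repressing / NA unsigned).
#' @param min_targets,min_degs inclusion thresholds (defaults 50 and 5).
#' @param deg_adj_p,deg_min_abs_lfc DEG definition (defaults 0.1 and 0.5).
#' @return data.frame, one row per retained TF.
#' @export
tf_target_enrichment <- function(de_results, tf_target_sets, min_targets = 50,
                                 min_degs = 5, deg_adj_p = 0.1,
                                 deg_min_abs_lfc = 0.5) {
  d <- as.data.frame(de_results)
  d$tf <- sub("^P_", "", d$perturbation)
  out <- lapply(names(tf_target_sets), function(tf) {
    sub <- d[d$tf == tf, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    ts <- tf_target_sets[[tf]]
    targets <- unique(ts$target)
    if (length(targets) < min_targets) return(NULL)
    deg <- !is.na(sub$adj_p) & sub$adj_p < deg_adj_p &
      abs(sub$log2fc) >= deg_min_abs_lfc
    if (sum(deg) < min_degs) return(NULL)
    in_set <- sub$response_gene %in% targets
    row <- .enrichment_row(tf,
                           a = sum(deg & in_set), b = sum(deg & !in_set),
                           c = sum(!deg & in_set), d = sum(!deg & !in_set),
                           alternative = "greater")
    row$n_degs <- sum(deg)
    row$n_targets <- length(targets)
    row$expected_fraction <- mean(in_set)
    row$observed_fraction <- mean(in_set[deg])
    mor <- ts$mor[match(sub$response_gene, ts$target)]
    hit <- deg & in_set
    expected_sign <- -mor  # TF knockdown inverts the annotated direction
    row$n_concordant <- sum(hit & !is.na(mor) & sign(sub$log2fc) == expected_sign)
    row$n_discordant <- sum(hit & !is.na(mor) & sign(sub$log2fc) == -expected_sign)
    row$n_unsigned <- sum(hit & is.na(mor))
    row
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Enrichment of observed pairs in a reference pair set
#'
#' 2x2 Fisher test over a universe of tested pairs: {observed (significant),
#' not} x {in reference, not}.
#'
#' @param observed_pairs,reference_pairs,universe_pairs character vectors of
#'   pair keys (e.g. "geneA geneB"); observed and reference must be subsets
#'   of the universe (reference pairs outside it are dropped).
#' @return one `EnrichmentResult` row.
#' @export
pair_enrichment <- function(observed_pairs, reference_pairs, universe_pairs) {
  universe_pairs <- unique(universe_pairs)
  observed_pairs <- intersect(unique(observed_pairs), universe_pairs)
  reference_pairs <- intersect(unique(reference_pairs), universe_pairs)
  obs <- universe_pairs %in% observed_pairs
  ref <- universe_pairs %in% reference_pairs
  .enrichment_row("pair_enrichment",
                  a = sum(obs & ref), b = sum(obs & !ref),
                  c = sum(!obs & ref), d = sum(!obs & !ref))
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric p per set (sets intersected with the universe),
#' BH-adjusted across sets; a set is enriched at `adj_p < alpha`.
#'
#' @param query_genes character vector, a subset of `universe`.
#' @param universe character vector of tested genes.
#' @param gene_sets named list of character vectors.
#' @param alpha enrichment threshold on adjusted p (default 0.05).
#' @return data.frame: set, n_set, n_overlap, p, adj_p, enriched.
#' @export
geneset_test <- function(query_genes, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query_genes)
  if (length(setdiff(query, universe)))
    stop_integrity("query genes outside the universe")
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, set))
    # P(X >= k), X ~ Hypergeom(|set| white, |U|-|set| black, |query| draws)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_query = length(query),
               n_overlap = k, p = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(res)
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$adj_p < alpha
  res
}
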