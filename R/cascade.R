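#' Build a CRE-to-network cascade from the two screens
#'
#' Layer 0 is the CRE-to-target edges of the high-confidence enhancer-like
#' links. Hop 1 collects genes differentially expressed when a layer-0
#' target gene was perturbed in the promoter screen (adjusted p and |log2FC|
#' gates, optionally truncated to the top-k strongest targets per source);
#' hop 2 repeats this from hop-1 genes. Layer membership follows
#' breadth-first semantics: a gene belongs to the first layer that reaches
#' it; edges back into earlier layers are kept in the edge list.
#'
#' @param enhancer_links table of high-confidence links (cre_id, gene_id);
#'   typically `prioritize(...)$links` filtered to `high_confidence`.
#' @param promoter_de promoter-screen `de_result` (perturbation labels with
#'   or without a "P_" prefix).
#' @param adj_p_max,min_abs_lfc edge gates (defaults 0.1 and 0.2; the 0.1
#'   LFC preset is also in use for dense network views).
#' @param top_k keep only each source's top-k edges by |log2FC|
#'   (default Inf = untruncated).
#' @return `cascade_network`: list with `layers` (cres, cre_targets,
#'   hop1_genes, hop2_genes, untested_targets), `edges` (source, sink,
#'   log2fc, adj_p, hop_level) and the thresholds used.
#' @export
build_cascade <- function(enhancer_links, promoter_de, adj_p_max = 0.1,
                          min_abs_lfc = 0.2, top_k = Inf) {
  d <- as.data.frame(promoter_de)
  d$gene <- sub("^P_", "", d$perturbation)
  pass <- !is.na(d$adj_p) & d$adj_p < adj_p_max & abs(d$log2fc) >= min_abs_lfc &
    d$gene != d$response_gene
  d <- d[pass, , drop = FALSE]
  if (is.finite(top_k) && nrow(d)) {
    keep <- unlist(tapply(seq_len(nrow(d)), d$gene, function(ix)
      ix[order(-abs(d$log2fc[ix]))][seq_len(min(top_k, length(ix)))]))
    d <- d[sort(unname(keep)), , drop = FALSE]
  }
  degs_of <- split(seq_len(nrow(d)), d$gene)
  perturbed <- unique(d$gene)
  perturbed_all <- unique(sub("^P_", "", as.data.frame(promoter_de)$perturbation))

  cre_targets <- unique(enhancer_links$gene_id)
  edges0 <- data.frame(source = enhancer_links$cre_id,
                       sink = enhancer_links$gene_id,
                       log2fc = if ("log2fc" %in% names(enhancer_links))
                         enhancer_links$log2fc else NA_real_,
                       adj_p = if ("adj_p" %in% names(enhancer_links))
                         enhancer_links$adj_p else NA_real_,
                       hop_level = 0L, stringsAsFactors = FALSE)

  edge_rows <- function(sources, hop) {
    ix <- unlist(degs_of[intersect(sources, names(degs_of))], use.names = FALSE)
    if (!length(ix)) return(NULL)
    data.frame(source = d$gene[ix], sink = d$response_gene[ix],
               log2fc = d$log2fc[ix], adj_p = d$adj_p[ix],
               hop_level = hop, stringsAsFactors = FALSE)
  }
  e1 <- edge_rows(cre_targets, 1L)
  hop1 <- as.character(setdiff(unique(e1$sink), cre_targets))
  e2 <- edge_rows(hop1, 2L)
  hop2 <- as.character(setdiff(unique(e2$sink), c(cre_targets, hop1)))

  structure(list(
    layers = list(
      cres = unique(enhancer_links$cre_id),
      cre_targets = cre_targets,
      hop1_genes = hop1,
      hop2_genes = hop2,
      untested_targets = setdiff(cre_targets, perturbed_all)),
    edges = rbind(edges0, e1, e2),
    thresholds = list(adj_p_max = adj_p_max, min_abs_lfc = min_abs_lfc,
                      top_k = top_k)
  ), class = "cascade_network")
}

#' Fraction of tested genes reached within two hops
#'
#' @param network a `cascade_network`.
#' @param n_tested_genes size of the tested-gene universe.
#' @return numeric fraction in [0, 1].
#' @export
reachable_fraction <- function(network, n_tested_genes) {
  reached <- unique(c(network$layers$cre_targets, network$layers$hop1_genes,
                      network$layers$hop2_genes))
  length(reached) / n_tested_genes
}

#' Per-disease regulatory programs with shared/unique term partition
#'
#' A disease's program is the union of CRE targets and hop-1 genes over the
#' CREs labeled with that disease (hop 2 feeds the cascade map but not the
#' programs by default). Each program is tested against `gene_sets` with the
#' hypergeometric test; a term is `shared` when enriched (adj p < alpha) in
#' more than `min_shared` diseases and `unique` when enriched in exactly one.
#'
#' @param network a `cascade_network`.
#' @param cre_diseases data.frame (cre_id, disease_labels comma-separated)
#'   or (cre_id, disease) long form.
#' @param gene_sets named list of gene sets.
#' @param universe tested-gene universe for the hypergeometric test.
#' @param alpha enrichment threshold on adjusted p (default 0.05).
#' @param min_shared a term is shared when enriched in more than this many
#'   diseases (default 5).
#' @param include_hop2 include hop-2 genes in programs (default FALSE).
#' @return list(programs, enrichment, shared_terms, unique_terms).
#' @export
disease_programs <- function(network, cre_diseases, gene_sets, universe,
                             alpha = 0.05, min_shared = 5,
                             include_hop2 = FALSE) {
  if ("disease_labels" %in% names(cre_diseases)) {
    lab <- strsplit(cre_diseases$disease_labels, ",", fixed = TRUE)
    long <- data.frame(cre_id = rep(cre_diseases$cre_id, lengths(lab)),
                       disease = unlist(lab), stringsAsFactors = FALSE)
  } else long <- cre_diseases

  e <- network$edges
  targets_of_cre <- split(e$sink[e$hop_level == 0], e$source[e$hop_level == 0])
  hop1_by_source <- split(e$sink[e$hop_level == 1], e$source[e$hop_level == 1])
  hop2_by_source <- split(e$sink[e$hop_level == 2], e$source[e$hop_level == 2])

  diseases <- unique(long$disease)
  programs <- lapply(diseases, function(dz) {
    cres <- intersect(long$cre_id[long$disease == dz], network$layers$cres)
    tg <- unique(unlist(targets_of_cre[cres], use.names = FALSE))
    h1 <- unique(unlist(hop1_by_source[intersect(tg, names(hop1_by_source))],
                        use.names = FALSE))
    prog <- union(tg, h1)
    if (include_hop2) {
      h2 <- unique(unlist(hop2_by_source[intersect(h1, names(hop2_by_source))],
                          use.names = FALSE))
      prog <- union(prog, h2)
    }
    intersect(prog, universe)
  })
  names(programs) <- diseases

  enr <- do.call(rbind, lapply(diseases, function(dz) {
    if (!length(programs[[dz]])) return(NULL)
    r <- geneset_test(programs[[dz]], universe, gene_sets, alpha)
    if (is.null(r)) return(NULL)
    cbind(disease = dz, r)
  }))
  if (!is.null(enr)) {
    n_enriched <- tapply(enr$enriched, enr$set, sum)
    shared <- names(n_enriched)[n_enriched > min_shared]
    uniq <- names(n_enriched)[n_enriched == 1]
  } else shared <- uniq <- character(0)
  list(programs = programs, enrichment = enr,
       shared_terms = shared, unique_terms = uniq)
}

#' @export
print.cascade_network <- function(x, ...) {
  cat(sprintf("cascade_network: %d CREs -> %d targets -> %d hop-1 -> %d hop-2 genes (%d edges)\n",
              length(x$layers$cres), length(x$layers$cre_targets),
              length(x$layers$hop1_genes), length(x$layers$hop2_genes),
              nrow(x$edges)))
  invisible(x)
}
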