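#' Proximal-mediation filter for distal links
#'
#' A distal link from CRE c fails when c has at least one significant
#' proximal link (to any target), since such a proximal effect could mediate
#' the distal one. Promoter-proximal links are never enhancer candidates and
#' always carry `mediation_pass = FALSE`.
#'
#' @param links `cre_gene_links` table.
#' @return the table with a logical `mediation_pass` column.
#' @export
mediation_filter <- function(links) {
  has_prox <- unique(links$cre_id[links$significant & links$position == "proximal"])
  links$mediation_pass <- links$position == "distal" &
    !(links$cre_id %in% has_prox)
  links
}

#' Distance bins for CRE-gene links
#'
#' Half-open bins: [0, 1.5 kb), [1.5 kb, 10 kb), [10 kb, 100 kb),
#' [100 kb, 1 Mb), [1 Mb, Inf).
#'
#' @param distance numeric distances in bp.
#' @return ordered factor of bin labels.
#' @export
distance_bins <- function(distance) {
  cut(distance, breaks = c(0, 1500, 1e4, 1e5, 1e6, Inf), right = FALSE,
      labels = c("<1.5kb", "1.5k-10k", "10k-100k", "100k-1M", ">1M"))
}

#' @rdname distance_bins
#' @param links table with a `distance` column.
#' @param closest_only if TRUE, keep only each CRE's closest-TSS link
#'   (used for bin summaries); the default keeps all links.
#' @export
assign_distance_bins <- function(links, closest_only = FALSE) {
  links$distance_bin <- distance_bins(links$distance)
  if (closest_only) {
    keep <- unlist(tapply(seq_len(nrow(links)), links$cre_id,
                          function(ix) ix[which.min(links$distance[ix])]))
    links <- links[sort(unname(keep)), , drop = FALSE]
  }
  links
}

#' Hi-C contact comparison, significant versus non-significant, per bin
#'
#' Within each distance bin, compares Hi-C contact values of significant
#' links against distance-matched (same-bin) non-significant tested pairs
#' with a two-sided Wilcoxon rank-sum test. Pairs without a contact value
#' are excluded and counted.
#'
#' @param links table with cre_id, gene_id, distance, significant.
#' @param contacts data.frame (cre_id, gene_id, contact).
#' @return per-bin data.frame: counts, median contacts, rank-sum p.
#' @export
hic_comparison <- function(links, contacts) {
  key <- paste(links$cre_id, links$gene_id)
  contact <- contacts$contact[match(key, paste(contacts$cre_id, contacts$gene_id))]
  bin <- distance_bins(links$distance)
  missing <- is.na(contact)
  out <- lapply(levels(bin), function(b) {
    inb <- !missing & !is.na(bin) & bin == b
    xs <- contact[inb & links$significant]
    xn <- contact[inb & !links$significant]
    p <- if (length(xs) >= 1 && length(xn) >= 1 && (length(xs) + length(xn)) > 2)
      suppressWarnings(stats::wilcox.test(xs, xn)$p.value) else NA_real_
    data.frame(distance_bin = b, n_sig = length(xs), n_nonsig = length(xn),
               n_missing_contact = sum(is.na(contact) & !is.na(bin) & bin == b),
               median_contact_sig = if (length(xs)) stats::median(xs) else NA_real_,
               median_contact_nonsig = if (length(xn)) stats::median(xn) else NA_real_,
               p_ranksum = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Same-TAD membership of CRE-gene pairs
#'
#' TRUE when no TAD boundary lies strictly between the CRE center and the
#' target TSS on the same chromosome.
#'
#' @param chrom,cre_center,tss vectors describing the pairs.
#' @param tads data.frame (chrom, start, end).
#' @return logical vector.
#' @export
same_tad <- function(chrom, cre_center, tss, tads) {
  .same_tad_lookup(chrom, cre_center, tss, tads)
}

#' TAD co-localization enrichment (Fisher's exact test)
#'
#' Builds the 2x2 table {significant, non-significant} x {same TAD, across
#' TADs} over distal tested pairs and reports the cross-ratio odds ratio and
#' the two-sided exact p.
#'
#' @param links table with cre_id, gene_id, significant and coordinates via
#'   `cre_table`/`annotation`, or precomputed logical `same_tad` column.
#' @param cre_table data.frame with cre_id, chrom, start, end.
#' @param annotation a [genome_annotation()].
#' @param tads TAD intervals (chrom, start, end).
#' @return list(odds_ratio, p, table).
#' @export
tad_test <- function(links, cre_table, annotation, tads) {
  ci <- match(links$cre_id, cre_table$cre_id)
  gi <- match(links$gene_id, annotation$gene_id)
  st <- same_tad(cre_table$chrom[ci],
                 floor((cre_table$start[ci] + cre_table$end[ci]) / 2),
                 annotation$tss[gi], tads)
  a <- sum(links$significant & st); b <- sum(links$significant & !st)
  cc <- sum(!links$significant & st); dd <- sum(!links$significant & !st)
  tab <- matrix(c(a, cc, b, dd), 2,
                dimnames = list(c("sig", "nonsig"), c("same_tad", "across_tads")))
  fr <- fisher_or(tab)
  list(odds_ratio = fr$odds_ratio, p = fr$p, table = tab, same_tad = st)
}

#' Assemble high-confidence enhancer-like links
#'
#' A link is high-confidence when it is significant, distal, passes the
#' proximal-mediation filter, and lies within `max_distance` of its target
#' TSS (CREs beyond 1 Mb are indistinguishable from non-significant elements
#' across chromatin and contact features, so the default cuts there). The
#' label is `enhancer` for negative log2FC under CRISPRi (repressing an
#' activator lowers the target) and `silencer` for positive.
#'
#' @param links `cre_gene_links` table.
#' @param cre_table data.frame with CRE coordinates and (optionally)
#'   chromatin signal columns atac/h3k27ac/h3k4me1/h3k4me3.
#' @param annotation a [genome_annotation()].
#' @param tads TAD intervals.
#' @param contacts Hi-C contact table (cre_id, gene_id, contact).
#' @param max_distance hard distance cut in bp (default 1 Mb); NULL disables.
#' @return list with `links` (class `prioritized_links`), `bin_summary`
#'   (per-bin medians of |log2FC| and chromatin signals over high-confidence
#'   links, closest-TSS link per CRE), `hic` (per-bin contact comparison)
#'   and `tad` (Fisher test).
#' @export
prioritize <- function(links, cre_table, annotation, tads, contacts,
                       max_distance = 1e6) {
  links <- mediation_filter(as.data.frame(links))
  links <- assign_distance_bins(links)
  key <- paste(links$cre_id, links$gene_id)
  links$hic_contact <- contacts$contact[match(key, paste(contacts$cre_id,
                                                         contacts$gene_id))]
  ci <- match(links$cre_id, cre_table$cre_id)
  gi <- match(links$gene_id, annotation$gene_id)
  links$same_tad <- same_tad(cre_table$chrom[ci],
                             floor((cre_table$start[ci] + cre_table$end[ci]) / 2),
                             annotation$tss[gi], tads)
  links$label <- ifelse(links$log2fc < 0, "enhancer", "silencer")
  links$high_confidence <- links$significant & links$position == "distal" &
    links$mediation_pass &
    (if (is.null(max_distance)) TRUE else links$distance <= max_distance)

  distal <- links[links$position == "distal", , drop = FALSE]
  tad <- tad_test(distal, cre_table, annotation, tads)
  hic <- hic_comparison(distal, contacts)

  hc <- links[links$high_confidence, , drop = FALSE]
  hc1 <- assign_distance_bins(hc, closest_only = TRUE)
  chroma <- intersect(c("atac", "h3k27ac", "h3k4me1", "h3k4me3"), names(cre_table))
  bin_summary <- do.call(rbind, lapply(levels(hc1$distance_bin), function(b) {
    sub <- hc1[!is.na(hc1$distance_bin) & hc1$distance_bin == b, , drop = FALSE]
    row <- data.frame(distance_bin = b, n = nrow(sub),
                      median_abs_log2fc = if (nrow(sub)) stats::median(abs(sub$log2fc)) else NA_real_)
    for (cn in chroma)
      row[[paste0("median_", cn)]] <- if (nrow(sub))
        stats::median(cre_table[[cn]][match(sub$cre_id, cre_table$cre_id)]) else NA_real_
    row
  }))

  class(links) <- c("prioritized_links", "data.frame")
  list(links = links, bin_summary = bin_summary, hic = hic, tad = tad,
       summary = list(
         n_high_confidence = nrow(hc),
         n_cres = length(unique(hc$cre_id)),
         n_target_genes = length(unique(hc$gene_id)),
         n_enhancer = sum(hc$label == "enhancer"),
         n_silencer = sum(hc$label == "silencer")))
}
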