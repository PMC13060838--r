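#' Run an expression with a temporary RNG state
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

default_annotation_params <- function() {
  list(
    n_genes        = 300L,
    n_chroms       = 3L,
    chrom_length   = 3e7,
    baseline_meanlog = 0,      # log expected UMI/cell before library scaling
    baseline_sdlog   = 1.1,
    dispersion_range = c(0.2, 0.8),
    body_meanlog     = log(3e4),
    body_sdlog       = 0.8
  )
}

default_regulatory_params <- function() {
  list(
    n_cres              = 120L,
    targets_per_cre     = 1.6,   # mean direct target genes per CRE
    silencer_fraction   = 0.27,  # fraction of direct links upregulated under CRISPRi
    enhancer_lfc_range  = c(0.05, 0.3),
    promoter_lfc_range  = c(1, 2.5),
    promoter_cre_fraction = 0.25,
    indirect_fraction   = 0,     # CREs given a trans-mediated distal decoy
    indirect_edge_lfc_range = c(0.3, 0.8),
    enhancer_distance_range = c(2e3, 2e6),  # log-uniform CRE center to anchor TSS
    cre_width_range     = c(300, 800),
    reference_knockdown_lfc = -2,
    tad_mean_size       = 8e5,
    hic_d0              = 5e3,
    hic_decay_power     = 1,
    hic_tad_boost       = 3,
    hic_link_boost      = 2,
    hic_noise_sdlog     = 0.4,
    chromatin_decay_scale = 2e5,
    same_tad_bias       = 0.75,  # enhancer CREs placed within the anchor's TAD

    trans_mean_out      = 1.0,   # mean out-degree of the trans gene network
    trans_lfc_range     = c(0.3, 1.2),
    panel_window        = 1e5,   # candidate genes within this window join the panel
    diseases            = c("IBD", "UC", "CD", "AS", "RA", "SLE", "MS", "PBCh",
                            "PSC", "T1D", "allergy", "asthma", "celiac", "liver"),
    eqtl_noise_rate     = 0.04,  # support rate among non-linked tested pairs
    seedless            = FALSE
  )
}

check_range <- function(x, name, lo = -Inf, hi = Inf, len = 1) {
  if (length(x) != len || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop_config("invalid value for '%s'", name)
  x
}

#' Generate a synthetic regulatory ground truth
#'
#' Builds a genome annotation and a planted regulatory truth: CREs with
#' disease labels and chromatin signals, direct CRE-to-gene links (promoter,
#' enhancer, silencer mechanisms plus optional trans-mediated indirect
#' decoys), an acyclic trans gene-gene network, TADs, distance-decaying
#' Hi-C contacts elevated within TADs, eQTL catalogs, and prediction-source
#' link lists. Deterministic for a fixed seed.
#'
#' @param annotation_params named list overriding [default_annotation_params()].
#' @param regulatory_params named list overriding [default_regulatory_params()].
#' @param seed integer seed.
#' @return list with elements `annotation` (a [genome_annotation()]) and
#'   `truth` (class `regulatory_truth`).
#' @export
generate_truth <- function(annotation_params = list(), regulatory_params = list(),
                           seed = 1L) {
  ap <- utils::modifyList(default_annotation_params(), annotation_params)
  rp <- utils::modifyList(default_regulatory_params(), regulatory_params)
  unknown <- setdiff(names(annotation_params), names(default_annotation_params()))
  if (length(unknown)) stop_config("unknown annotation parameter(s): %s",
                                   paste(unknown, collapse = ", "))
  unknown <- setdiff(names(regulatory_params), names(default_regulatory_params()))
  if (length(unknown)) stop_config("unknown regulatory parameter(s): %s",
                                   paste(unknown, collapse = ", "))

  check_range(ap$n_genes, "n_genes", lo = 2)
  check_range(ap$n_chroms, "n_chroms", lo = 1)
  check_range(rp$silencer_fraction, "silencer_fraction", 0, 1)
  check_range(rp$indirect_fraction, "indirect_fraction", 0, 1)
  check_range(rp$promoter_cre_fraction, "promoter_cre_fraction", 0, 1)
  check_range(rp$enhancer_lfc_range, "enhancer_lfc_range", lo = 0, len = 2)
  if (diff(rp$enhancer_lfc_range) < 0) stop_config("invalid value for 'enhancer_lfc_range'")
  check_range(rp$targets_per_cre, "targets_per_cre", lo = 1)

  with_seed(seed, {
    ann <- .gen_annotation(ap)
    truth <- .gen_truth(ann, rp)
  })
  list(annotation = ann, truth = truth)
}

.gen_annotation <- function(ap) {
  n <- ap$n_genes
  chroms <- paste0("chr", seq_len(ap$n_chroms))
  chrom <- sample(chroms, n, replace = TRUE)
  tss <- floor(runif(n, 1e5, ap$chrom_length - 1e5))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- pmax(2e3, round(rlnorm(n, ap$body_meanlog, ap$body_sdlog)))
  body_start <- ifelse(strand == "+", tss, tss + 1 - len)
  body_end   <- ifelse(strand == "+", tss + len, tss + 1)
  body_start <- pmax(0, body_start)
  genome_annotation(data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom, tss = as.integer(tss), strand = strand,
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    baseline_mean = rlnorm(n, ap$baseline_meanlog, ap$baseline_sdlog),
    dispersion = runif(n, ap$dispersion_range[1], ap$dispersion_range[2]),
    stringsAsFactors = FALSE
  ))
}

.gen_truth <- function(ann, rp) {
  n_cres <- rp$n_cres
  cre_id <- sprintf("CRE%04d", seq_len(n_cres))
  is_promoter_cre <- runif(n_cres) < rp$promoter_cre_fraction

  # TADs first (CRE placement is TAD-aware): exponential tiling per chromosome
  tads <- do.call(rbind, lapply(unique(ann$chrom), function(ch) {
    L <- max(ann$body_end[ann$chrom == ch]) + 2.5e6
    b <- 0
    repeat {
      nb <- b[length(b)] + max(5e4, round(rexp(1, 1 / rp$tad_mean_size)))
      b <- c(b, nb)
      if (nb > L) break
    }
    data.frame(chrom = ch, start = as.integer(b[-length(b)]),
               end = as.integer(b[-1]), stringsAsFactors = FALSE)
  }))
  tads$name <- sprintf("TAD%04d", seq_len(nrow(tads)))

  # anchor genes weighted by expression: screens read out expressed panels
  w <- ann$baseline_mean / sum(ann$baseline_mean)
  anchor <- sample(nrow(ann), n_cres, replace = TRUE, prob = w)
  width <- round(runif(n_cres, rp$cre_width_range[1], rp$cre_width_range[2]))

  # enhancer CREs preferentially share the anchor's TAD: most functional
  # distal regulation acts within domains
  dist <- numeric(n_cres); side <- numeric(n_cres)
  for (i in seq_len(n_cres)) {
    if (is_promoter_cre[i]) {
      dist[i] <- round(runif(1, 0, 500)); side[i] <- sample(c(-1, 1), 1)
      next
    }
    want_same_tad <- runif(1) < rp$same_tad_bias
    for (try in 1:20) {
      dist[i] <- round(exp(runif(1, log(rp$enhancer_distance_range[1]),
                                 log(rp$enhancer_distance_range[2]))))
      side[i] <- sample(c(-1, 1), 1)
      if (!want_same_tad) break
      cen <- ann$tss[anchor[i]] + side[i] * dist[i]
      if (cen >= 0 && .same_tad_lookup(ann$chrom[anchor[i]], cen,
                                       ann$tss[anchor[i]], tads)) break
    }
  }
  center <- ann$tss[anchor] + side * round(dist)
  start <- pmax(0, center - floor(width / 2))
  end <- start + width

  cres <- data.frame(
    cre_id = cre_id, chrom = ann$chrom[anchor],
    start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE
  )
  n_lab <- 1L + rpois(n_cres, 0.8)
  cres$disease_labels <- vapply(n_lab, function(k)
    paste(sample(rp$diseases, min(k, length(rp$diseases))), collapse = ","),
    character(1))

  # direct CRE-gene links: anchor plus extra nearby genes up to the mean degree
  links <- vector("list", n_cres)
  for (i in seq_len(n_cres)) {
    k <- 1L + rpois(1, rp$targets_per_cre - 1)
    gi <- anchor[i]
    same_chrom <- which(ann$chrom == ann$chrom[gi])
    near <- same_chrom[abs(ann$tss[same_chrom] - ann$tss[gi]) < 5e5 &
                         same_chrom != gi]
    extra <- if (k > 1 && length(near)) sample(near, min(k - 1, length(near))) else integer(0)
    tgt <- c(gi, extra)
    mech <- if (is_promoter_cre[i]) c("promoter", rep("enhancer", length(extra)))
            else rep("enhancer", length(tgt))
    sil <- runif(length(tgt)) < rp$silencer_fraction & mech != "promoter"
    mech[sil] <- "silencer"
    mag <- ifelse(mech == "promoter",
                  runif(length(tgt), rp$promoter_lfc_range[1], rp$promoter_lfc_range[2]),
                  runif(length(tgt), rp$enhancer_lfc_range[1], rp$enhancer_lfc_range[2]))
    lfc <- ifelse(sil, mag, -mag)  # promoters and enhancers knock down; silencers go up
    links[[i]] <- data.frame(cre_id = cre_id[i], gene_id = ann$gene_id[tgt],
                             lfc = lfc, mechanism = mech, stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)
  links <- links[!duplicated(links[c("cre_id", "gene_id")]), ]

  # trans gene-gene network: acyclic by index ordering
  n_genes <- nrow(ann)
  out_deg <- rpois(n_genes, rp$trans_mean_out)
  te <- vector("list", n_genes)
  for (g in seq_len(n_genes - 1)) {
    k <- min(out_deg[g], n_genes - g)
    if (k > 0) {
      cand <- (g + 1):n_genes
      to <- cand[sample.int(length(cand), k)]
      mag <- runif(k, rp$trans_lfc_range[1], rp$trans_lfc_range[2])
      te[[g]] <- data.frame(from = ann$gene_id[g], to = ann$gene_id[to],
                            lfc = mag * sample(c(-1, 1), k, replace = TRUE),
                            stringsAsFactors = FALSE)
    }
  }
  trans_edges <- do.call(rbind, te)
  if (is.null(trans_edges))
    trans_edges <- data.frame(from = character(), to = character(), lfc = numeric())

  # trans-mediated distal decoys: a proximal link plus an engineered trans edge
  # decoys are planted only on promoter-context CREs so the mediating link is
  # proximal: that is the confound the mediation filter is designed to remove
  n_ind <- round(rp$indirect_fraction * n_cres)
  if (n_ind > 0) {
    cand <- which(is_promoter_cre)
    pick <- if (length(cand)) cand[sample.int(length(cand), min(n_ind, length(cand)))]
            else integer(0)
    ind <- vector("list", length(pick))
    for (j in seq_along(pick)) {
      i <- pick[j]
      p_gene <- anchor[i]
      same_chrom <- setdiff(which(ann$chrom == ann$chrom[p_gene]), p_gene)
      distal <- same_chrom[abs(ann$tss[same_chrom] - ((start[i] + end[i]) / 2)) > 1e4 &
                             abs(ann$tss[same_chrom] - ((start[i] + end[i]) / 2)) < 8e5]
      if (!length(distal)) next
      d_gene <- sample(distal, 1)
      e_mag <- runif(1, rp$indirect_edge_lfc_range[1], rp$indirect_edge_lfc_range[2])
      e_sign <- if (runif(1) < rp$silencer_fraction) 1 else -1
      edge_lfc <- e_sign * e_mag
      trans_edges <- rbind(trans_edges, data.frame(
        from = ann$gene_id[p_gene], to = ann$gene_id[d_gene], lfc = edge_lfc))
      p_lfc <- links$lfc[links$cre_id == cre_id[i] & links$gene_id == ann$gene_id[p_gene]][1]
      if (is.na(p_lfc)) next
      ind[[j]] <- data.frame(
        cre_id = cre_id[i], gene_id = ann$gene_id[d_gene],
        lfc = edge_lfc * (p_lfc / rp$reference_knockdown_lfc),
        mechanism = "indirect", stringsAsFactors = FALSE)
    }
    ind <- do.call(rbind, ind)
    if (!is.null(ind)) {
      ind <- ind[!paste(ind$cre_id, ind$gene_id) %in%
                   paste(links$cre_id, links$gene_id), , drop = FALSE]
      links <- rbind(links, ind)
    }
  }
  trans_edges <- trans_edges[!duplicated(trans_edges[c("from", "to")]), ]

  # tested panel per CRE: window genes + nearest flank + linked genes
  cc <- floor((cres$start + cres$end) / 2)
  panels <- do.call(rbind, lapply(seq_len(n_cres), function(i) {
    sc <- which(ann$chrom == cres$chrom[i])
    d <- abs(ann$tss[sc] - cc[i])
    keep <- sc[d <= rp$panel_window]
    up <- sc[ann$tss[sc] < cc[i]]; dn <- sc[ann$tss[sc] > cc[i]]
    flank <- c(if (length(up)) up[which.max(ann$tss[up])],
               if (length(dn)) dn[which.min(ann$tss[dn])])
    g <- unique(c(keep, flank,
                  match(links$gene_id[links$cre_id == cre_id[i]], ann$gene_id)))
    data.frame(cre_id = cre_id[i], gene_id = ann$gene_id[g], stringsAsFactors = FALSE)
  }))

  pan_key <- paste(panels$cre_id, panels$gene_id)
  pan_cre <- match(panels$cre_id, cre_id)
  pan_gene <- match(panels$gene_id, ann$gene_id)
  pan_d <- abs(cc[pan_cre] - ann$tss[pan_gene])

  # chromatin: class-conditional lognormals scaled by distance decay of the
  # CRE to its nearest linked (or anchor) TSS
  decay <- 1 / (1 + dist / rp$chromatin_decay_scale)
  decay[is_promoter_cre] <- 1
  ln <- function(mu, sd = 0.3) rlnorm(n_cres, log(mu), sd)
  cres$atac     <- ln(5) * pmax(decay, 0.15)
  cres$h3k27ac  <- ifelse(is_promoter_cre, ln(4), ln(6) * pmax(decay, 0.15))
  cres$h3k4me1  <- ifelse(is_promoter_cre, ln(2), ln(5) * pmax(decay, 0.15))
  cres$h3k4me3  <- ifelse(is_promoter_cre, ln(8), ln(1))

  # Hi-C contacts on every tested pair: power-law decay, TAD boost, link boost
  same_tad <- .same_tad_lookup(cres$chrom[pan_cre], cc[pan_cre],
                               ann$tss[pan_gene], tads)
  is_true <- pan_key %in% paste(links$cre_id, links$gene_id)[links$mechanism != "indirect"]
  contact <- (rp$hic_d0 / (rp$hic_d0 + pan_d))^rp$hic_decay_power *
    ifelse(same_tad, rp$hic_tad_boost, 1) *
    ifelse(is_true, rp$hic_link_boost, 1) *
    rlnorm(length(pan_d), 0, rp$hic_noise_sdlog)
  hic <- data.frame(cre_id = panels$cre_id, gene_id = panels$gene_id,
                    contact = contact, stringsAsFactors = FALSE)

  true_pairs <- paste(links$cre_id, links$gene_id)[links$mechanism != "indirect"]
  nontrue_key <- setdiff(pan_key, true_pairs)
  sample_pairs <- function(frac_true, noise_rate) {
    tp <- true_pairs[runif(length(true_pairs)) < frac_true]
    np <- nontrue_key[runif(length(nontrue_key)) < noise_rate]
    keys <- unique(c(tp, np))
    sp <- strsplit(keys, " ", fixed = TRUE)
    data.frame(cre_id = vapply(sp, `[`, "", 1), gene_id = vapply(sp, `[`, "", 2),
               stringsAsFactors = FALSE)
  }

  prediction_sources <- list(
    within_100kb = panels[pan_d <= rp$panel_window, , drop = FALSE],
    nearest_gene = {
      nn <- tapply(seq_len(nrow(panels)), panels$cre_id, function(ix) ix[which.min(pan_d[ix])])
      panels[unlist(nn), , drop = FALSE]
    },
    grn  = sample_pairs(0.6, 0.25),
    re2g = sample_pairs(0.5, 0.10),
    eqtl = sample_pairs(0.2, 0.02)
  )

  eqtl_catalogs <- list(
    cd4_t_cell  = sample_pairs(0.40, rp$eqtl_noise_rate / 2),
    whole_blood = sample_pairs(0.30, rp$eqtl_noise_rate),
    other_tissue = sample_pairs(0.0, rp$eqtl_noise_rate * 2)
  )

  structure(list(
    cres = cres, links = links, trans_edges = trans_edges, tads = tads,
    hic = hic, panels = panels, prediction_sources = prediction_sources,
    eqtl_catalogs = eqtl_catalogs, diseases = rp$diseases,
    params = rp
  ), class = "regulatory_truth")
}

# TRUE when no TAD boundary lies strictly between the two positions
.same_tad_lookup <- function(chrom, pos1, pos2, tads) {
  res <- logical(length(chrom))
  for (ch in unique(chrom)) {
    b <- sort(unique(c(tads$start[tads$chrom == ch], tads$end[tads$chrom == ch])))
    ix <- which(chrom == ch)
    lo <- pmin(pos1[ix], pos2[ix]); hi <- pmax(pos1[ix], pos2[ix])
    n_between <- findInterval(hi - 1e-9, b) - findInterval(lo + 1e-9, b)
    res[ix] <- n_between <= 0
  }
  res
}

#' @export
print.regulatory_truth <- function(x, ...) {
  cat(sprintf(paste0("regulatory_truth: %d CREs, %d direct links ",
                     "(%d promoter, %d enhancer, %d silencer), %d trans edges\n"),
              nrow(x$cres), sum(x$links$mechanism != "indirect"),
              sum(x$links$mechanism == "promoter"),
              sum(x$links$mechanism == "enhancer"),
              sum(x$links$mechanism == "silencer"),
              nrow(x$trans_edges)))
  invisible(x)
}
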