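#' Screen configuration
#'
#' Parameters of a simulated CRISPRi screen. Defaults mirror the design of
#' pooled screens in primary CD4+ T cells: three donors, 8 gRNAs per CRE
#' (3 per gene in promoter-screen mode), roughly 80% of cells uniquely
#' assigned to one gRNA, lognormal library sizes and gene-wise lognormal
#' donor effects.
#'
#' @param n_cells number of cells to simulate.
#' @param n_donors number of donors; cells are split evenly at random.
#' @param grna_per_target gRNAs designed per target (8 for CREs, 3 for genes).
#' @param n_nontargeting number of non-targeting control gRNAs.
#' @param unique_assignment_rate fraction of cells with exactly one gRNA.
#' @param mean_umi_per_cell expected total UMI per cell.
#' @param library_size_cv coefficient of variation of the lognormal per-cell
#'   library size factor.
#' @param donor_effect_sd sdlog of the gene-wise lognormal donor multiplier.
#' @param propagate_trans if TRUE, perturbation effects take one multiplicative
#'   hop through the trans gene network.
#' @param reference_knockdown_lfc log2 fold change of a full promoter knockdown;
#'   trans-edge effects are scaled by (direct effect / this reference).
#' @param grna_active_fraction probability that a targeting gRNA is active.
#' @param seed integer seed.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(n_cells = 10000L, n_donors = 3L, grna_per_target = 8L,
                          n_nontargeting = 30L, unique_assignment_rate = 0.8,
                          mean_umi_per_cell = 2000, library_size_cv = 0.3,
                          donor_effect_sd = 0.15, propagate_trans = FALSE,
                          reference_knockdown_lfc = -2,
                          grna_active_fraction = 1, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_donors = as.integer(n_donors),
              grna_per_target = as.integer(grna_per_target),
              n_nontargeting = as.integer(n_nontargeting),
              unique_assignment_rate = unique_assignment_rate,
              mean_umi_per_cell = mean_umi_per_cell,
              library_size_cv = library_size_cv,
              donor_effect_sd = donor_effect_sd,
              propagate_trans = isTRUE(propagate_trans),
              reference_knockdown_lfc = reference_knockdown_lfc,
              grna_active_fraction = grna_active_fraction,
              seed = as.integer(seed))
  for (f in c("n_cells", "n_donors", "grna_per_target", "n_nontargeting"))
    if (cfg[[f]] <= 0 && f != "n_nontargeting")
      stop_config("invalid value for '%s': must be positive", f)
  if (cfg$n_nontargeting < 1) stop_config("invalid value for 'n_nontargeting'")
  if (cfg$unique_assignment_rate <= 0 || cfg$unique_assignment_rate > 1)
    stop_config("invalid value for 'unique_assignment_rate': must be in (0, 1]")
  if (cfg$mean_umi_per_cell <= 0) stop_config("invalid value for 'mean_umi_per_cell'")
  if (cfg$library_size_cv < 0) stop_config("invalid value for 'library_size_cv'")
  if (cfg$donor_effect_sd < 0) stop_config("invalid value for 'donor_effect_sd'")
  if (cfg$grna_active_fraction < 0 || cfg$grna_active_fraction > 1)
    stop_config("invalid value for 'grna_active_fraction'")
  class(cfg) <- "screen_config"
  cfg
}

#' Target tables for the two screen designs
#'
#' @param truth a `regulatory_truth`.
#' @param control_promoter_genes gene ids perturbed as positive-control
#'   promoters alongside the CREs.
#' @return data.frame with `target_id`, `target_type`, `on_target_gene`,
#'   `on_target_lfc` (NA means use the config reference knockdown).
#' @export
cre_screen_targets <- function(truth, control_promoter_genes = character()) {
  rbind(
    data.frame(target_id = truth$cres$cre_id, target_type = "cre",
               on_target_gene = NA_character_, on_target_lfc = NA_real_,
               stringsAsFactors = FALSE),
    if (length(control_promoter_genes))
      data.frame(target_id = paste0("P_", control_promoter_genes),
                 target_type = "control_promoter",
                 on_target_gene = control_promoter_genes,
                 on_target_lfc = NA_real_, stringsAsFactors = FALSE)
  )
}

#' @rdname cre_screen_targets
#' @param gene_ids genes perturbed at their promoters.
#' @param on_target_lfc optional per-gene knockdown log2FC (recycled).
#' @export
promoter_screen_targets <- function(gene_ids, on_target_lfc = NA_real_) {
  data.frame(target_id = paste0("P_", gene_ids), target_type = "promoter",
             on_target_gene = gene_ids,
             on_target_lfc = rep_len(on_target_lfc, length(gene_ids)),
             stringsAsFactors = FALSE)
}

# per-target named vectors of log2 effects on genes
.target_effects <- function(targets, annotation, truth, config) {
  trans <- truth$trans_edges
  ref <- config$reference_knockdown_lfc
  out <- vector("list", nrow(targets))
  names(out) <- targets$target_id
  for (i in seq_len(nrow(targets))) {
    tt <- targets$target_type[i]
    if (tt == "cre") {
      lk <- truth$links[truth$links$cre_id == targets$target_id[i] &
                          truth$links$mechanism != "indirect", ]
      eff <- structure(lk$lfc, names = lk$gene_id)
    } else if (tt %in% c("promoter", "control_promoter")) {
      g <- targets$on_target_gene[i]
      if (!g %in% annotation$gene_id)
        stop_integrity("promoter target gene '%s' absent from annotation", g)
      e <- targets$on_target_lfc[i]
      if (is.na(e)) e <- ref
      eff <- structure(e, names = g)
    } else {
      eff <- numeric(0)
    }
    if (config$propagate_trans && length(eff) && nrow(trans)) {
      hop <- trans[trans$from %in% names(eff), , drop = FALSE]
      if (nrow(hop)) {
        add <- hop$lfc * (eff[hop$from] / ref)
        names(add) <- hop$to
        add <- add[!names(add) %in% names(eff)]
        if (length(add)) {
          add <- tapply(add, names(add), sum)
          eff <- c(eff, structure(as.numeric(add), names = names(add)))
        }
      }
    }
    out[[i]] <- eff
  }
  out
}

#' Simulate a CRISPRi screen with single-cell NB counts
#'
#' Counts for cell i and gene g are NB with mean
#' `s_i * d(donor_i, g) * baseline_g * 2^effect(target_i, g)` and gene-wise
#' dispersion, where `s_i` is a lognormal library-size factor and `d` a
#' gene-wise lognormal donor multiplier. Effects apply the planted link LFCs
#' of the cell's (active) gRNA target; with `propagate_trans` they additionally
#' take one multiplicative hop through the trans network.
#'
#' @param annotation a [genome_annotation()].
#' @param truth a `regulatory_truth` from [generate_truth()].
#' @param config a [screen_config()].
#' @param targets target table from [cre_screen_targets()] or
#'   [promoter_screen_targets()].
#' @return A `screen_dataset`: list with `counts` (genes x cells sparse
#'   dgCMatrix), `cells`, `assignments`, `grna_table`, `config`.
#' @export
simulate_screen <- function(annotation, truth, config, targets) {
  if (!inherits(config, "screen_config")) stop_config("config must be a screen_config")
  bad <- setdiff(truth$links$gene_id, annotation$gene_id)
  if (length(bad))
    stop_integrity("truth links reference gene(s) absent from annotation: %s",
                   paste(utils::head(bad, 3), collapse = ", "))

  with_seed(config$seed, {
    n_cells <- config$n_cells
    n_genes <- nrow(annotation)

    targets <- rbind(targets,
                     data.frame(target_id = "non-targeting",
                                target_type = "non-targeting",
                                on_target_gene = NA_character_,
                                on_target_lfc = NA_real_,
                                stringsAsFactors = FALSE))
    n_per <- ifelse(targets$target_type == "non-targeting",
                    config$n_nontargeting, config$grna_per_target)
    grna_table <- data.frame(
      grna_id = unlist(lapply(seq_len(nrow(targets)), function(i)
        sprintf("%s_g%d", targets$target_id[i], seq_len(n_per[i])))),
      target_id = rep(targets$target_id, n_per),
      target_type = rep(targets$target_type, n_per),
      stringsAsFactors = FALSE)
    grna_table$active <- runif(nrow(grna_table)) < config$grna_active_fraction |
      grna_table$target_type == "non-targeting"

    cells <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(n_cells)),
      donor = sprintf("donor%d", sample(config$n_donors, n_cells, replace = TRUE)),
      panel = "panel1", stringsAsFactors = FALSE)

    # assignment multiplicity: unique / doublet / none
    u <- runif(n_cells)
    n_grna <- ifelse(u < config$unique_assignment_rate, 1L,
                     ifelse(u < config$unique_assignment_rate +
                              (1 - config$unique_assignment_rate) / 2, 2L, 0L))
    g1 <- sample(nrow(grna_table), n_cells, replace = TRUE)
    g2 <- sample(nrow(grna_table), n_cells, replace = TRUE)
    rows1 <- which(n_grna >= 1)
    rows2 <- which(n_grna == 2)
    assignments <- rbind(
      data.frame(cell_id = cells$cell_id[rows1],
                 grna_id = grna_table$grna_id[g1[rows1]],
                 target_id = grna_table$target_id[g1[rows1]],
                 stringsAsFactors = FALSE),
      data.frame(cell_id = cells$cell_id[rows2],
                 grna_id = grna_table$grna_id[g2[rows2]],
                 target_id = grna_table$target_id[g2[rows2]],
                 stringsAsFactors = FALSE))
    assignments <- assignments[order(match(assignments$cell_id, cells$cell_id)), ]
    rownames(assignments) <- NULL

    # effect of the first (expressed) gRNA only; inactive guides do nothing
    eff_list <- .target_effects(targets, annotation, truth, config)
    cell_target <- rep(NA_integer_, n_cells)
    cell_target[rows1] <- match(grna_table$target_id[g1[rows1]], targets$target_id)
    cell_target[rows1][!grna_table$active[g1[rows1]]] <- NA_integer_

    eff_by_gene <- vector("list", n_genes)
    names(eff_by_gene) <- annotation$gene_id
    for (ti in seq_along(eff_list)) {
      e <- eff_list[[ti]]
      for (j in seq_along(e)) {
        gi <- match(names(e)[j], annotation$gene_id)
        eff_by_gene[[gi]] <- c(eff_by_gene[[gi]], structure(e[[j]], names = ti))
      }
    }
    cells_by_target <- split(seq_len(n_cells), cell_target)

    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    s <- rlnorm(n_cells, -sdlog^2 / 2, sdlog)
    donor_idx <- as.integer(factor(cells$donor,
                                   levels = sprintf("donor%d", seq_len(config$n_donors))))
    d_mat <- matrix(rlnorm(n_genes * config$n_donors,
                           -config$donor_effect_sd^2 / 2, config$donor_effect_sd),
                    nrow = n_genes)

    scale <- config$mean_umi_per_cell / sum(annotation$baseline_mean)
    base <- annotation$baseline_mean * scale

    ii <- vector("list", n_genes); jj <- vector("list", n_genes); xx <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      mu <- s * d_mat[g, donor_idx] * base[g]
      e <- eff_by_gene[[g]]
      if (length(e)) for (j in seq_along(e)) {
        idx <- cells_by_target[[as.character(as.integer(names(e)[j]))]]
        if (length(idx)) mu[idx] <- mu[idx] * 2^e[[j]]
      }
      y <- rnbinom(n_cells, size = 1 / annotation$dispersion[g], mu = mu)
      nz <- which(y > 0)
      ii[[g]] <- rep.int(g, length(nz)); jj[[g]] <- nz; xx[[g]] <- y[nz]
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = unlist(xx),
      dims = c(n_genes, n_cells),
      dimnames = list(annotation$gene_id, cells$cell_id))

    structure(list(counts = counts, cells = cells, assignments = assignments,
                   grna_table = grna_table, config = config),
              class = "screen_dataset")
  })
}

#' @export
print.screen_dataset <- function(x, ...) {
  n_assigned <- length(unique(x$assignments$cell_id))
  cat(sprintf("screen_dataset: %d genes x %d cells; %d gRNAs over %d targets; %d cells with >=1 gRNA\n",
              nrow(x$counts), ncol(x$counts), nrow(x$grna_table),
              length(unique(x$grna_table$target_id)), n_assigned))
  invisible(x)
}
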