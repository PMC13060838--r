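PIPELINE_STAGES <- c("simulate", "qc", "de", "links", "prioritize",
                     "enrich", "cascade")

.need <- function(outdir, files, stage_hint) {
  paths <- file.path(outdir, files)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop_dependency("missing upstream output %s; run stage '%s' first",
                    basename(miss[1]), stage_hint)
  invisible(paths)
}

.manifest_add <- function(outdir, stage, inputs, outputs, config, seed) {
  path <- file.path(outdir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else list()
  digest <- function(fs) {
    fs <- fs[file.exists(fs)]
    as.list(structure(unname(tools::md5sum(fs)), names = basename(fs)))
  }
  man[[stage]] <- list(stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
                       seed = seed, inputs = digest(file.path(outdir, inputs)),
                       outputs = digest(file.path(outdir, outputs)),
                       config = config)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

stage_simulate <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_truth(cfg$synth$annotation_params, cfg$synth$regulatory_params,
                       seed = cfg$seed)
  ann <- gt$annotation; truth <- gt$truth
  write_truth(ann, truth, file.path(outdir, "truth"))

  ctrl_genes <- ann$gene_id[order(-ann$baseline_mean)][
    seq_len(min(cfg$synth$cre_screen$n_control_promoters, nrow(ann)))]
  cre_cfg <- screen_config(
    n_cells = cfg$synth$cre_screen$n_cells,
    grna_per_target = cfg$synth$cre_screen$grna_per_target,
    seed = cfg$seed + 1L)
  cre_ds <- simulate_screen(ann, truth, cre_cfg,
                            cre_screen_targets(truth, ctrl_genes))
  write_screen_dataset(cre_ds, file.path(outdir, "cre_screen"))
  writeLines(paste0("P_", ctrl_genes), file.path(outdir, "control_promoters.txt"))

  link_genes <- unique(truth$links$gene_id)
  n_tg <- cfg$synth$promoter_screen$n_target_genes
  extra <- setdiff(ann$gene_id[order(-ann$baseline_mean)], link_genes)
  prom_genes <- utils::head(c(link_genes, extra), n_tg)
  prom_cfg <- screen_config(
    n_cells = cfg$synth$promoter_screen$n_cells,
    grna_per_target = cfg$synth$promoter_screen$grna_per_target,
    propagate_trans = isTRUE(cfg$synth$promoter_screen$propagate_trans),
    seed = cfg$seed + 2L)
  prom_ds <- simulate_screen(ann, truth, prom_cfg,
                             promoter_screen_targets(prom_genes))
  write_screen_dataset(prom_ds, file.path(outdir, "promoter_screen"))
  c("truth/annotation.tsv", "cre_screen/matrix.mtx", "promoter_screen/matrix.mtx",
    "control_promoters.txt")
}

.load_screen <- function(outdir, which) {
  .need(outdir, file.path(which, c("matrix.mtx", "cells.tsv", "assignments.tsv",
                                   "grnas.tsv")), "simulate")
  read_screen_dataset(file.path(outdir, which))
}

stage_qc <- function(cfg, outdir) {
  outs <- character(0)
  for (which in c("cre_screen", "promoter_screen")) {
    ds <- .load_screen(outdir, which)
    f <- filter_and_assign(ds, cfg$qc$min_umi, cfg$qc$min_genes,
                           cfg$qc$min_cells_per_grna)
    write_tsv(f$assignments, file.path(outdir, which, "assignments_resolved.tsv"))
    write_json_summary(f$qc_summary, file.path(outdir, which, "qc_summary.json"))
    if (which == "promoter_screen") {
      tg <- f$grna_table
      prom <- tg$target_id[tg$target_type %in% c("promoter", "control_promoter")]
      target_gene_of <- structure(as.list(sub("^P_", "", unique(prom))),
                                  names = unique(prom))
      kd <- knockdown_table(f, target_gene_of, cfg$qc$normalization_scale,
                            min_cells = cfg$qc$min_cells_per_grna)
      write_tsv(kd, file.path(outdir, "knockdown.tsv"))
      outs <- c(outs, "knockdown.tsv")
    }
    outs <- c(outs, file.path(which, "assignments_resolved.tsv"))
  }
  outs
}

.load_filtered <- function(cfg, outdir, which) {
  .need(outdir, file.path(which, "assignments_resolved.tsv"), "qc")
  ds <- .load_screen(outdir, which)
  asn <- read_tsv(file.path(outdir, which, "assignments_resolved.tsv"))
  keep <- match(asn$cell_id, ds$cells$cell_id)
  ds$counts <- ds$counts[, keep, drop = FALSE]
  ds$cells <- ds$cells[keep, , drop = FALSE]
  ds$assignments <- asn
  ds
}

stage_de <- function(cfg, outdir) {
  truth <- read_truth(file.path(outdir, "truth"))
  cre <- .load_filtered(cfg, outdir, "cre_screen")
  pb <- pseudobulk(cre, cfg$de$min_cells_per_group)
  panels <- split(truth$truth$panels$gene_id, truth$truth$panels$cre_id)
  ctrl <- readLines(file.path(outdir, "control_promoters.txt"))
  panel_list <- c(panels, structure(
    lapply(sub("^P_", "", ctrl), function(g) g), names = ctrl))
  de_cre <- nb_wald(pb, tested_genes = panel_list,
                    shrink_weight = cfg$de$shrink_weight)
  write_tsv(as.data.frame(de_cre), file.path(outdir, "de_cre.tsv"))

  prom <- .load_filtered(cfg, outdir, "promoter_screen")
  pbp <- pseudobulk(prom, cfg$de$min_cells_per_group)
  vg <- variable_genes(pbp, cfg$de$n_variable_genes)
  de_prom <- nb_wald(pbp, tested_genes = vg,
                     shrink_weight = cfg$de$shrink_weight)
  write_tsv(as.data.frame(de_prom), file.path(outdir, "de_promoter.tsv"))
  writeLines(vg, file.path(outdir, "variable_genes.txt"))
  c("de_cre.tsv", "de_promoter.tsv", "variable_genes.txt")
}

stage_links <- function(cfg, outdir) {
  .need(outdir, "de_cre.tsv", "de")
  de_cre <- read_tsv(file.path(outdir, "de_cre.tsv"))
  class(de_cre) <- c("de_result", "data.frame")
  tr <- read_truth(file.path(outdir, "truth"))
  ctrl <- readLines(file.path(outdir, "control_promoters.txt"))
  cl <- call_links(de_cre, tr$truth$cres, tr$annotation,
                   control_promoter_ids = ctrl, fdr = cfg$links$fdr,
                   min_abs_lfc = cfg$links$min_abs_lfc,
                   proximal_window = cfg$links$proximal_window,
                   prediction_sources = tr$truth$prediction_sources)
  write_tsv(as.data.frame(cl$links), file.path(outdir, "links.tsv"))
  write_tsv(cl$audit, file.path(outdir, "audit.tsv"))
  src_names <- names(tr$truth$prediction_sources)
  targeted <- setdiff(src_names, c("within_100kb", "nearest_gene"))
  if (!length(targeted)) targeted <- src_names
  bench <- benchmark_predictions(cl$links, tr$truth$prediction_sources,
                                 targeted_sources = targeted)
  bench$fold_vs_unpredicted <- attr(bench, "fold_vs_unpredicted")
  write_tsv(bench, file.path(outdir, "benchmark.tsv"))
  write_json_summary(cl$summary, file.path(outdir, "link_summary.json"))
  c("links.tsv", "audit.tsv", "benchmark.tsv", "link_summary.json")
}

stage_prioritize <- function(cfg, outdir) {
  .need(outdir, "links.tsv", "links")
  links <- read_tsv(file.path(outdir, "links.tsv"))
  links$prediction_sources <- as.character(links$prediction_sources %||% "")
  links$prediction_sources[is.na(links$prediction_sources)] <- ""
  tr <- read_truth(file.path(outdir, "truth"))
  pr <- prioritize(links, tr$truth$cres, tr$annotation, tr$truth$tads,
                   tr$truth$hic,
                   max_distance = if (isTRUE(cfg$prioritize$apply_max_distance))
                     cfg$prioritize$max_distance else NULL)
  write_tsv(as.data.frame(pr$links), file.path(outdir, "prioritized.tsv"))
  write_tsv(pr$bin_summary, file.path(outdir, "bin_summary.tsv"))
  write_tsv(pr$hic, file.path(outdir, "hic_comparison.tsv"))
  write_json_summary(list(odds_ratio = pr$tad$odds_ratio, p = pr$tad$p,
                          table = as.integer(pr$tad$table)),
                     file.path(outdir, "tad_test.json"))
  write_json_summary(pr$summary, file.path(outdir, "prioritize_summary.json"))
  c("prioritized.tsv", "bin_summary.tsv", "hic_comparison.tsv",
    "tad_test.json", "prioritize_summary.json")
}

stage_enrich <- function(cfg, outdir) {
  .need(outdir, c("prioritized.tsv", "de_promoter.tsv"), "prioritize")
  links <- read_tsv(file.path(outdir, "prioritized.tsv"))
  links$prediction_sources <- as.character(links$prediction_sources %||% "")
  links$prediction_sources[is.na(links$prediction_sources)] <- ""
  tr <- read_truth(file.path(outdir, "truth"))
  eq <- eqtl_enrichment(links, tr$truth$eqtl_catalogs)
  write_tsv(eq, file.path(outdir, "enrichment_eqtl.tsv"))

  de_prom <- read_tsv(file.path(outdir, "de_promoter.tsv"))
  te <- tr$truth$trans_edges
  tf_sets <- lapply(split(seq_len(nrow(te)), te$from), function(ix)
    data.frame(target = te$to[ix], mor = sign(te$lfc[ix])))
  tf <- tf_target_enrichment(de_prom, tf_sets,
                             min_targets = cfg$enrichment$min_targets,
                             min_degs = cfg$enrichment$min_degs,
                             deg_adj_p = cfg$enrichment$deg_adj_p,
                             deg_min_abs_lfc = cfg$enrichment$deg_min_abs_lfc)
  if (!is.null(tf)) write_tsv(tf, file.path(outdir, "enrichment_tf.tsv"))
  else write_tsv(data.frame(), file.path(outdir, "enrichment_tf.tsv"))

  # cis-trans pair reference: the trans network plays the eQTL-pair catalog
  sig <- !is.na(de_prom$adj_p) & de_prom$adj_p < cfg$de$fdr
  gene_of <- sub("^P_", "", de_prom$perturbation)
  universe <- paste(gene_of, de_prom$response_gene)
  observed <- universe[sig]
  reference <- with_seed(cfg$seed + 7L, {
    tp <- paste(te$from, te$to)
    c(tp[runif(length(tp)) < 0.5], sample(universe, min(50, length(universe))))
  })
  pe <- pair_enrichment(observed, reference, universe)
  write_json_summary(as.list(pe), file.path(outdir, "enrichment_pairs.json"))
  c("enrichment_eqtl.tsv", "enrichment_tf.tsv", "enrichment_pairs.json")
}

stage_cascade <- function(cfg, outdir) {
  .need(outdir, c("prioritized.tsv", "de_promoter.tsv", "variable_genes.txt"),
        "prioritize")
  links <- read_tsv(file.path(outdir, "prioritized.tsv"))
  hc <- links[links$high_confidence, , drop = FALSE]
  de_prom <- read_tsv(file.path(outdir, "de_promoter.tsv"))
  net <- build_cascade(hc, de_prom, adj_p_max = cfg$cascade$adj_p_max,
                       min_abs_lfc = cfg$cascade$min_abs_lfc,
                       top_k = cfg$cascade$top_k)
  write_tsv(net$edges, file.path(outdir, "cascade_edges.tsv"))
  layers <- data.frame(
    gene = c(net$layers$cre_targets, net$layers$hop1_genes, net$layers$hop2_genes),
    layer = rep(c("cre_target", "hop1", "hop2"),
                c(length(net$layers$cre_targets), length(net$layers$hop1_genes),
                  length(net$layers$hop2_genes))))
  write_tsv(layers, file.path(outdir, "cascade_layers.tsv"))

  n_tested <- length(unique(de_prom$response_gene))
  tr <- read_truth(file.path(outdir, "truth"))
  universe <- unique(de_prom$response_gene)
  gene_sets <- with_seed(cfg$seed + 11L, {
    n_sets <- 20L
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, min(max(5, rpois(1, 15)), length(universe))))
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    sets
  })
  dp <- disease_programs(net, tr$truth$cres, gene_sets, universe,
                         min_shared = cfg$cascade$min_shared,
                         include_hop2 = isTRUE(cfg$cascade$include_hop2_in_programs))
  for (dz in names(dp$programs))
    write_tsv(data.frame(gene = dp$programs[[dz]]),
              file.path(outdir, sprintf("programs_%s.tsv", dz)))
  su <- rbind(
    if (length(dp$shared_terms)) data.frame(term = dp$shared_terms, status = "shared"),
    if (length(dp$unique_terms)) data.frame(term = dp$unique_terms, status = "unique"))
  write_tsv(su %||% data.frame(term = character(), status = character()),
            file.path(outdir, "shared_unique_terms.tsv"))
  write_json_summary(list(
    n_cre_targets = length(net$layers$cre_targets),
    n_hop1 = length(net$layers$hop1_genes),
    n_hop2 = length(net$layers$hop2_genes),
    n_untested_targets = length(net$layers$untested_targets),
    reachable_fraction = reachable_fraction(net, n_tested),
    n_tested_genes = n_tested), file.path(outdir, "cascade_summary.json"))
  c("cascade_edges.tsv", "cascade_layers.tsv", "shared_unique_terms.tsv",
    "cascade_summary.json")
}

#' Run the pipeline stages in dependency order
#'
#' Stages: simulate, qc, de, links, prioritize, enrich, cascade. Each stage
#' reads its inputs from and writes its outputs to `outdir`, and records a
#' manifest entry (input/output md5 digests, config snapshot, seed,
#' timestamp). A missing upstream output raises a dependency error naming
#' the stage to run first.
#'
#' @param config path to a YAML config, or a config list from
#'   [load_config()].
#' @param outdir working directory for all stage inputs/outputs.
#' @param stages character vector of stages, or "all".
#' @param seed optional global seed override.
#' @return invisibly, the manifest path.
#' @export
run_pipeline <- function(config = NULL, outdir, stages = "all", seed = NULL) {
  cfg <- if (is.character(config) || is.null(config)) load_config(config) else config
  validate_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop_config("unknown stage(s): %s (valid: %s)",
                               paste(bad, collapse = ", "),
                               paste(PIPELINE_STAGES, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  runner <- list(simulate = stage_simulate, qc = stage_qc, de = stage_de,
                 links = stage_links, prioritize = stage_prioritize,
                 enrich = stage_enrich, cascade = stage_cascade)
  for (st in stages) {
    message(sprintf("[crecascade] stage %s", st))
    outs <- runner[[st]](cfg, outdir)
    .manifest_add(outdir, st, character(0), outs, cfg, cfg$seed)
  }
  invisible(file.path(outdir, "manifest.json"))
}
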