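test_that("truth generation is deterministic under a fixed seed", {
  a <- generate_truth(list(n_genes = 80), list(n_cres = 20), seed = 42)
  b <- generate_truth(list(n_genes = 80), list(n_cres = 20), seed = 42)
  expect_identical(a, b)
  c <- generate_truth(list(n_genes = 80), list(n_cres = 20), seed = 43)
  expect_false(identical(a$truth$cres, c$truth$cres))
})

test_that("invalid generator parameters name the offending field", {
  expect_error(generate_truth(regulatory_params = list(silencer_fraction = 1.5)),
               "silencer_fraction", class = "crecascade_config_error")
  expect_error(generate_truth(regulatory_params = list(bogus_knob = 1)),
               "bogus_knob", class = "crecascade_config_error")
  expect_error(generate_truth(annotation_params = list(n_genes = 0)),
               "n_genes", class = "crecascade_config_error")
})

test_that("silencer_fraction 0 yields only negative planted effects", {
  gt <- generate_truth(list(n_genes = 100),
                       list(n_cres = 40, silencer_fraction = 0,
                            indirect_fraction = 0.2), seed = 5)
  expect_true(all(gt$truth$links$lfc < 0))
})

test_that("truth invariants: referenced ids exist and enhancer effects are weak", {
  gt <- quick_truth(seed = 9)
  tr <- gt$truth
  expect_true(all(tr$links$gene_id %in% gt$annotation$gene_id))
  expect_true(all(tr$links$cre_id %in% tr$cres$cre_id))
  expect_true(all(tr$hic$cre_id %in% tr$cres$cre_id))
  enh <- abs(tr$links$lfc[tr$links$mechanism %in% c("enhancer", "silencer")])
  expect_true(all(enh >= 0.05 & enh <= 0.3))
  # trans network is acyclic by construction (edges follow gene index order)
  ord <- match(tr$trans_edges$from, gt$annotation$gene_id) <
    match(tr$trans_edges$to, gt$annotation$gene_id)
  expect_true(all(ord))
})

test_that("Hi-C contacts decay with distance and are elevated within TADs", {
  gt <- generate_truth(list(n_genes = 400, n_chroms = 4),
                       list(n_cres = 400, panel_window = 2e6,
                            same_tad_bias = 0), seed = 11)
  tr <- gt$truth
  cc <- floor((tr$cres$start + tr$cres$end) / 2)
  ci <- match(tr$hic$cre_id, tr$cres$cre_id)
  gi <- match(tr$hic$gene_id, gt$annotation$gene_id)
  d <- abs(cc[ci] - gt$annotation$tss[gi])
  near <- tr$hic$contact[d <= 1e4]
  far <- tr$hic$contact[d > 1e6]
  expect_gt(length(near), 50)
  expect_gt(length(far), 50)
  expect_gt(mean(near), mean(far))
  st <- same_tad(tr$cres$chrom[ci], cc[ci], gt$annotation$tss[gi], tr$tads)
  mid <- d > 1e4 & d < 5e5  # compare at matched intermediate distances
  expect_gt(median(tr$hic$contact[st & mid]), median(tr$hic$contact[!st & mid]))
})

test_that("screen simulation is deterministic and honors assignment rates", {
  gt <- quick_truth(seed = 2, n_genes = 60, n_cres = 10)
  d1 <- quick_screen(gt, n_cells = 1500, seed = 3)
  d2 <- quick_screen(gt, n_cells = 1500, seed = 3)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$assignments, d2$assignments)
  tab <- table(d1$assignments$cell_id)
  frac_unique <- sum(tab == 1) / ncol(d1$counts)
  expect_gt(frac_unique, 0.75)
  expect_lt(frac_unique, 0.85)
})

test_that("null screen: perturbed and control means agree for every gene", {
  gt <- quick_truth(seed = 4, n_genes = 40, n_cres = 6)
  gt$truth$links$lfc <- 0
  ds <- quick_screen(gt, n_cells = 6000, seed = 5)
  asn <- ds$assignments[!duplicated(ds$assignments$cell_id) &
                          !ds$assignments$cell_id %in%
                          ds$assignments$cell_id[duplicated(ds$assignments$cell_id)], ]
  pert <- asn$cell_id[asn$target_id != "non-targeting"]
  ctrl <- asn$cell_id[asn$target_id == "non-targeting"]
  lib <- Matrix::colSums(ds$counts)
  norm <- ds$counts %*% Matrix::Diagonal(x = 1 / lib)
  colnames(norm) <- colnames(ds$counts)
  mp <- Matrix::rowMeans(norm[, pert])
  mc <- Matrix::rowMeans(norm[, ctrl])
  expect_true(all(abs(log2(mp / mc)) < 0.35))
  expect_lt(mean(abs(log2(mp / mc))), 0.08)
})

test_that("a planted lfc of -1 halves normalized expression", {
  ann <- tiny_annotation()
  ann$baseline_mean <- c(10, 40, 30, 30)  # target well expressed but a small
                                          # library share, so normalization is
                                          # not distorted by its own knockdown
  truth <- structure(list(
    cres = data.frame(cre_id = "CRE1", chrom = "chr1", start = 99000L,
                      end = 99500L, disease_labels = "IBD",
                      atac = 1, h3k27ac = 1, h3k4me1 = 1, h3k4me3 = 1),
    links = data.frame(cre_id = "CRE1", gene_id = "gA", lfc = -1,
                       mechanism = "promoter"),
    trans_edges = data.frame(from = character(), to = character(), lfc = numeric()),
    tads = data.frame(chrom = "chr1", start = 0L, end = 1000000L, name = "T1"),
    hic = data.frame(cre_id = character(), gene_id = character(), contact = numeric()),
    panels = data.frame(cre_id = "CRE1", gene_id = "gA"),
    prediction_sources = list(), eqtl_catalogs = list(), diseases = "IBD",
    params = NULL), class = "regulatory_truth")
  cfg <- screen_config(n_cells = 8000, unique_assignment_rate = 1,
                       grna_per_target = 2, n_nontargeting = 2,
                       mean_umi_per_cell = 500, donor_effect_sd = 0,
                       library_size_cv = 0, seed = 8)
  ds <- simulate_screen(ann, truth, cfg,
                        data.frame(target_id = "CRE1", target_type = "cre",
                                   on_target_gene = NA, on_target_lfc = NA))
  asn <- ds$assignments
  pert <- asn$cell_id[asn$target_id == "CRE1"]
  ctrl <- asn$cell_id[asn$target_id == "non-targeting"]
  expect_gt(length(pert), 2000)
  ratio <- mean(ds$counts["gA", pert]) / mean(ds$counts["gA", ctrl])
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
})

test_that("non-targeting counts match NB moments: var/mean = 1 + alpha*mean", {
  ann <- tiny_annotation()
  ann$baseline_mean <- c(40, 20, 10, 5)
  ann$dispersion <- rep(0.5, 4)
  truth <- structure(list(
    cres = data.frame(cre_id = character(), chrom = character(),
                      start = integer(), end = integer()),
    links = data.frame(cre_id = character(), gene_id = character(),
                       lfc = numeric(), mechanism = character()),
    trans_edges = data.frame(from = character(), to = character(), lfc = numeric()),
    tads = data.frame(chrom = character(), start = integer(), end = integer()),
    hic = data.frame(), panels = data.frame(),
    prediction_sources = list(), eqtl_catalogs = list(), diseases = character(),
    params = NULL), class = "regulatory_truth")
  cfg <- screen_config(n_cells = 20000, unique_assignment_rate = 1,
                       n_nontargeting = 4, mean_umi_per_cell = 75,
                       library_size_cv = 0, donor_effect_sd = 0, seed = 21)
  ds <- simulate_screen(ann, truth, cfg,
                        data.frame(target_id = character(),
                                   target_type = character(),
                                   on_target_gene = character(),
                                   on_target_lfc = numeric()))
  for (g in c("gA", "gB")) {
    y <- as.numeric(ds$counts[g, ])
    vmr <- var(y) / mean(y)
    expected <- 1 + 0.5 * mean(y)
    expect_gt(vmr / expected, 0.85)
    expect_lt(vmr / expected, 1.15)
  }
})

test_that("trans propagation adds downstream effects only when enabled", {
  ann <- tiny_annotation()
  ann$baseline_mean <- c(40, 40, 40, 40)
  truth <- structure(list(
    cres = data.frame(cre_id = character(), chrom = character(),
                      start = integer(), end = integer()),
    links = data.frame(cre_id = character(), gene_id = character(),
                       lfc = numeric(), mechanism = character()),
    trans_edges = data.frame(from = "gA", to = "gB", lfc = -1),
    tads = data.frame(chrom = character(), start = integer(), end = integer()),
    hic = data.frame(), panels = data.frame(),
    prediction_sources = list(), eqtl_catalogs = list(), diseases = character(),
    params = NULL), class = "regulatory_truth")
  tg <- promoter_screen_targets("gA")
  ratio_gb <- function(propagate) {
    # library_size_cv 0 and donor_effect_sd 0: raw count means are unbiased,
    # avoiding the composition shift that per-cell normalization introduces
    # when a large target is knocked down
    cfg <- screen_config(n_cells = 8000, unique_assignment_rate = 1,
                         grna_per_target = 3, n_nontargeting = 3,
                         mean_umi_per_cell = 400, donor_effect_sd = 0,
                         library_size_cv = 0,
                         propagate_trans = propagate, seed = 13)
    ds <- simulate_screen(ann, truth, cfg, tg)
    asn <- ds$assignments
    pert <- asn$cell_id[asn$target_id == "P_gA"]
    ctrl <- asn$cell_id[asn$target_id == "non-targeting"]
    mean(ds$counts["gB", pert]) / mean(ds$counts["gB", ctrl])
  }
  expect_lt(abs(log2(ratio_gb(FALSE))), 0.15)
  # full knockdown of gA passes the full edge lfc (-1) to gB
  expect_lt(abs(log2(ratio_gb(TRUE)) - (-1)), 0.2)
})

test_that("ground truth round-trips through the plain-text writers", {
  gt <- quick_truth(seed = 6, n_genes = 50, n_cres = 12)
  dir <- withr::local_tempdir()
  write_truth(gt$annotation, gt$truth, dir)
  back <- read_truth(dir)
  expect_equal(as.data.frame(back$annotation), as.data.frame(gt$annotation),
               tolerance = 1e-12)
  expect_equal(back$truth$links, gt$truth$links, tolerance = 1e-12)
  expect_equal(back$truth$cres$cre_id, gt$truth$cres$cre_id)
  expect_equal(back$truth$hic$contact, gt$truth$hic$contact, tolerance = 1e-6)
  expect_setequal(names(back$truth$prediction_sources),
                  names(gt$truth$prediction_sources))
  expect_equal(back$truth$eqtl_catalogs$cd4_t_cell,
               gt$truth$eqtl_catalogs$cd4_t_cell)
})
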