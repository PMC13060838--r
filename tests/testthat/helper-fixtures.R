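# Small fixtures built in code at test time.

tiny_annotation <- function() {
  genome_annotation(data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    tss = c(100000L, 160000L, 500000L, 50000L),
    strand = c("+", "-", "+", "+"),
    body_start = c(100000L, 120000L, 500000L, 50000L),
    body_end = c(150000L, 160001L, 540000L, 80000L),
    baseline_mean = c(5, 3, 2, 1),
    dispersion = c(0.4, 0.4, 0.4, 0.4)))
}

quick_truth <- function(seed = 1, n_genes = 150, n_cres = 30, ...) {
  generate_truth(list(n_genes = n_genes), c(list(n_cres = n_cres), list(...)),
                 seed = seed)
}

quick_screen <- function(gt, n_cells = 4000, seed = 7, targets = NULL, ...) {
  cfg <- screen_config(n_cells = n_cells, seed = seed, ...)
  if (is.null(targets)) targets <- cre_screen_targets(gt$truth)
  simulate_screen(gt$annotation, gt$truth, cfg, targets)
}

# random annotation + CREs used by the classification property tests
random_class_fixture <- function(seed, n_genes = 30, n_cres = 50) {
  set.seed(seed)
  n <- n_genes
  tss <- sort(sample(5e4:2e6, n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(2e3:5e4, n, replace = TRUE)
  ann <- genome_annotation(data.frame(
    gene_id = sprintf("g%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    tss = tss, strand = strand,
    body_start = ifelse(strand == "+", tss, tss + 1 - len),
    body_end = ifelse(strand == "+", tss + len, tss + 1),
    baseline_mean = rep(1, n), dispersion = rep(0.4, n)))
  start <- sample(1e4:2.1e6, n_cres)
  cres <- data.frame(cre_id = sprintf("c%03d", 1:n_cres),
                     chrom = sample(c("chr1", "chr2"), n_cres, replace = TRUE),
                     start = start, end = start + sample(200:900, n_cres, TRUE))
  list(ann = ann, cres = cres)
}
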