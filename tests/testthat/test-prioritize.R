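mk_links <- function(cre_id, gene_id, position, significant, log2fc = -0.2,
                     distance = 50000) {
  data.frame(cre_id = cre_id, gene_id = gene_id, position = position,
             significant = significant, log2fc = log2fc, distance = distance,
             adj_p = ifelse(significant, 0.01, 0.5), stringsAsFactors = FALSE)
}

test_that("mediation filter blocks distal links of CREs with proximal hits", {
  links <- rbind(
    mk_links("c1", "gD1", "distal", TRUE),                # only distal -> pass
    mk_links("c2", "gP", "proximal", TRUE, distance = 500),
    mk_links("c2", "gD2", "distal", TRUE),                # blocked via gP
    mk_links("c3", "gP2", "proximal", FALSE, distance = 900),
    mk_links("c3", "gD3", "distal", TRUE))                # NS proximal: pass
  out <- mediation_filter(links)
  expect_true(out$mediation_pass[out$gene_id == "gD1"])
  expect_false(out$mediation_pass[out$gene_id == "gD2"])
  expect_true(out$mediation_pass[out$gene_id == "gD3"])
  expect_false(any(out$mediation_pass[out$position == "proximal"]))
})

test_that("mediation filter equals the set-difference oracle on random fixtures", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- 60
    links <- mk_links(sprintf("c%d", sample(12, n, TRUE)),
                      sprintf("g%d", 1:n),
                      sample(c("proximal", "distal"), n, TRUE),
                      runif(n) < 0.4)
    out <- mediation_filter(links)
    expect_identical(which(out$mediation_pass), mediation_oracle(links))
  }
})

test_that("distance bins are half-open with the documented boundaries", {
  d <- c(0, 1499, 1500, 9999, 10000, 99999, 1e5, 999999, 1e6, 2e6)
  expect_equal(as.character(distance_bins(d)),
               c("<1.5kb", "<1.5kb", "1.5k-10k", "1.5k-10k", "10k-100k",
                 "10k-100k", "100k-1M", "100k-1M", ">1M", ">1M"))
})

test_that("closest-TSS deduplication keeps one link per CRE for bin summaries", {
  links <- rbind(mk_links("c1", "gA", "distal", TRUE, distance = 5e4),
                 mk_links("c1", "gB", "distal", TRUE, distance = 2e4),
                 mk_links("c2", "gC", "distal", TRUE, distance = 3e5))
  out <- assign_distance_bins(links, closest_only = TRUE)
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene_id, c("gB", "gC"))
})

test_that("hic_comparison detects constructed per-bin contact enrichment and handles nulls", {
  set.seed(90)
  n <- 400
  links <- mk_links(sprintf("c%d", 1:n), sprintf("g%d", 1:n), "distal",
                    rep(c(TRUE, FALSE), n / 2),
                    distance = exp(runif(n, log(2000), log(5e6))))
  # null: identical distributions
  contacts <- data.frame(cre_id = links$cre_id, gene_id = links$gene_id,
                         contact = rlnorm(n, 0, 0.5))
  hc0 <- hic_comparison(links, contacts)
  expect_true(all(hc0$p_ranksum[!is.na(hc0$p_ranksum)] > 0.001))

  # constructed: significant pairs at 2x the contact within each bin
  contacts2 <- contacts
  contacts2$contact[links$significant] <- contacts2$contact[links$significant] * 2
  hc2 <- hic_comparison(links, contacts2)
  pop <- !is.na(hc2$p_ranksum) & hc2$n_sig >= 20 & hc2$n_nonsig >= 20
  expect_true(all(hc2$p_ranksum[pop] < 0.01))
  expect_true(all(hc2$median_contact_sig[pop] > hc2$median_contact_nonsig[pop]))

  # degenerate: a bin with no significant pairs yields NA, no test
  links3 <- links[!links$significant | links$distance > 1e4, ]
  hc3 <- hic_comparison(links3, contacts)
  expect_true(is.na(hc3$p_ranksum[hc3$distance_bin == "1.5k-10k"]))
})

test_that("tad_test reproduces the cross-ratio and the hypergeometric p", {
  ann <- tiny_annotation()
  tads <- data.frame(chrom = "chr1", start = c(0L, 200000L),
                     end = c(200000L, 600000L))
  # same_tad: no boundary strictly between CRE center and TSS
  expect_true(same_tad("chr1", 150000, 100000, tads))
  expect_false(same_tad("chr1", 250000, 100000, tads))

  # table [[3,1],[2,4]] -> OR 6; p equals full enumeration (N = 10)
  fr <- fisher_or(matrix(c(3, 2, 1, 4), 2))
  expect_equal(fr$odds_ratio, 6)
  expect_equal(fr$p, fisher_enum_oracle(matrix(c(3, 2, 1, 4), 2)),
               tolerance = 1e-12)
  # null table
  fr0 <- fisher_or(matrix(c(5, 5, 5, 5), 2))
  expect_equal(fr0$odds_ratio, 1)
  expect_equal(fr0$p, 1)
})

test_that("prioritize assembles high-confidence enhancer-like links", {
  ann <- tiny_annotation()
  cres <- data.frame(
    cre_id = c("c1", "c2", "c3"), chrom = "chr1",
    start = c(150000L, 99500L, 2200000L) - 300L,
    end = c(150000L, 99500L, 2200000L) + 300L,
    atac = c(5, 8, 1), h3k27ac = c(6, 3, 1), h3k4me1 = c(5, 2, 1),
    h3k4me3 = c(1, 9, 1))
  # c1: significant intergenic-style distal link at 50 kb, no proximal hits
  # c2: proximal hit plus a distal link (blocked by mediation)
  # c3: significant distal link at ~2.1 Mb (beyond the 1 Mb cut)
  links <- rbind(
    mk_links("c1", "gA", "distal", TRUE, log2fc = -0.3, distance = 50000),
    mk_links("c2", "gA", "proximal", TRUE, log2fc = -1.5, distance = 500),
    mk_links("c2", "gC", "distal", TRUE, log2fc = -0.2, distance = 399500),
    mk_links("c3", "gA", "distal", TRUE, log2fc = 0.25, distance = 2100000))
  tads <- data.frame(chrom = "chr1", start = 0L, end = 3000000L)
  contacts <- data.frame(cre_id = links$cre_id, gene_id = links$gene_id,
                         contact = c(2, 5, 1, 0.1))
  pr <- prioritize(links, cres, ann, tads, contacts)
  out <- pr$links
  expect_true(out$high_confidence[out$cre_id == "c1"])
  expect_equal(out$label[out$cre_id == "c1"], "enhancer")
  expect_false(out$high_confidence[out$cre_id == "c2" & out$gene_id == "gC"])
  expect_false(out$high_confidence[out$cre_id == "c3"])  # max_distance cut
  expect_equal(pr$summary$n_high_confidence, 1)

  # subset chain: high-confidence within significant distal within all links
  hc <- out[out$high_confidence, ]
  sd <- out[out$significant & out$position == "distal", ]
  expect_true(all(paste(hc$cre_id, hc$gene_id) %in% paste(sd$cre_id, sd$gene_id)))
  expect_lt(nrow(hc), nrow(out))
  expect_equal(pr$summary$n_enhancer + pr$summary$n_silencer,
               pr$summary$n_high_confidence)

  # disabling the distance cut readmits the 2.1 Mb link
  pr2 <- prioritize(links, cres, ann, tads, contacts, max_distance = NULL)
  expect_true(pr2$links$high_confidence[pr2$links$cre_id == "c3"])
  expect_equal(pr2$links$label[pr2$links$cre_id == "c3"], "silencer")
})

test_that("planted decay produces non-increasing bin medians of signal and effect", {
  gt <- generate_truth(list(n_genes = 600, n_chroms = 4),
                       list(n_cres = 400, promoter_cre_fraction = 0,
                            targets_per_cre = 1, same_tad_bias = 0.5),
                       seed = 95)
  tr <- gt$truth
  # links table straight from the ground truth (all significant)
  ci <- match(tr$links$cre_id, tr$cres$cre_id)
  gi <- match(tr$links$gene_id, gt$annotation$gene_id)
  links <- data.frame(
    cre_id = tr$links$cre_id, gene_id = tr$links$gene_id,
    log2fc = tr$links$lfc * (1 / (1 + cre_tss_distance(
      tr$cres$start[ci], tr$cres$end[ci], gt$annotation$tss[gi]) / 2e5)),
    adj_p = 0.01, significant = TRUE, position = "distal",
    distance = cre_tss_distance(tr$cres$start[ci], tr$cres$end[ci],
                                gt$annotation$tss[gi]))
  pr <- prioritize(links, tr$cres, gt$annotation, tr$tads, tr$hic)
  bs <- pr$bin_summary
  mid <- bs[bs$distance_bin %in% c("1.5k-10k", "10k-100k", "100k-1M"), ]
  expect_true(all(diff(mid$median_atac) <= 0))
  expect_true(all(diff(mid$median_h3k27ac) <= 0))
  expect_true(all(diff(mid$median_abs_log2fc) <= 0))
})
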