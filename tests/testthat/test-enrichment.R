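test_that("fisher_or computes the cross-ratio and exact enumeration p", {
  f <- fisher_or(matrix(c(10, 2, 5, 20), 2))
  expect_equal(f$odds_ratio, 20)
  expect_false(f$corrected)
  f1 <- fisher_or(matrix(c(1, 1, 1, 1), 2))
  expect_equal(f1$odds_ratio, 1)
  expect_equal(f1$p, 1)

  set.seed(100)
  for (i in 1:40) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) > 30 || sum(tab) == 0) next
    expect_equal(fisher_or(tab)$p, fisher_enum_oracle(tab), tolerance = 1e-9)
    expect_equal(fisher_or(tab, "greater")$p,
                 fisher_enum_oracle(tab, "greater"), tolerance = 1e-9)
  }
})

test_that("fisher_or symmetry: transposition keeps p, row swap inverts the OR", {
  set.seed(101)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    a <- fisher_or(tab)
    expect_equal(fisher_or(t(tab))$p, a$p, tolerance = 1e-12)
    expect_equal(fisher_or(tab[2:1, ])$odds_ratio, 1 / a$odds_ratio,
                 tolerance = 1e-12)
  }
  expect_error(fisher_or(matrix(c(-1, 1, 1, 1), 2)),
               class = "crecascade_config_error")
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  f <- fisher_or(matrix(c(5, 0, 0, 5), 2))
  expect_true(f$corrected)
  expect_true(is.finite(f$odds_ratio))
  expect_equal(f$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("eqtl enrichment: degenerate, null, and constructed catalogs", {
  n <- 2000
  links <- data.frame(cre_id = sprintf("c%d", 1:n), gene_id = sprintf("g%d", 1:n),
                      significant = c(rep(TRUE, 400), rep(FALSE, n - 400)),
                      interaction_class = "intergenic-distal",
                      prediction_sources = "grn", stringsAsFactors = FALSE)
  # catalog supporting exactly the significant set: corrected infinite OR
  exact <- links[links$significant, c("cre_id", "gene_id")]
  r <- eqtl_enrichment(links, list(exact = exact))
  expect_true(r$corrected)
  expect_gt(r$log_or, 5)

  # random catalogs: mean |log OR| small over repetitions
  set.seed(110)
  lors <- replicate(60, {
    idx <- sample(n, 400)
    eqtl_enrichment(links, list(r = links[idx, c("cre_id", "gene_id")]))$log_or
  })
  expect_lt(mean(abs(lors)), 0.2)

  # 5x enrichment among significant links is recovered
  set.seed(111)
  idx <- c(sample(1:400, 200), sample(401:n, 125))
  r5 <- eqtl_enrichment(links, list(e = links[idx, c("cre_id", "gene_id")]))
  expect_gt(r5$log_or, log(5) - 1)
  expect_lt(r5$p, 0.001)
})

test_that("log OR sign flips when the support labels are complemented", {
  n <- 200
  links <- data.frame(cre_id = sprintf("c%d", 1:n), gene_id = sprintf("g%d", 1:n),
                      significant = rep(c(TRUE, FALSE), c(50, 150)),
                      prediction_sources = "x", stringsAsFactors = FALSE)
  set.seed(112)
  idx <- c(sample(1:50, 30), sample(51:n, 30))
  a <- eqtl_enrichment(links, list(k = links[idx, c("cre_id", "gene_id")]))
  b <- eqtl_enrichment(links, list(k = links[-idx, c("cre_id", "gene_id")]))
  expect_equal(a$log_or, -b$log_or, tolerance = 1e-9)
})

test_that("TF target enrichment applies thresholds and splits concordance", {
  set.seed(120)
  genes <- sprintf("g%03d", 1:300)
  mk_de <- function(tf, degs, lfcs) {
    data.frame(perturbation = paste0("P_", tf), response_gene = genes,
               log2fc = ifelse(genes %in% degs,
                               lfcs[match(genes, degs)], rnorm(300, 0, 0.05)),
               se = 0.1,
               wald_p = ifelse(genes %in% degs, 1e-5, runif(300, 0.2, 1)),
               adj_p = ifelse(genes %in% degs, 1e-4, runif(300, 0.3, 1)),
               stringsAsFactors = FALSE)
  }
  targets <- genes[1:60]
  # TF1: 10 DEGs, 8 in its target set, signs matching knockdown expectation
  degs1 <- c(targets[1:8], genes[200:201])
  de1 <- mk_de("TF1", degs1, c(rep(-1, 4), rep(1, 4), -1, 1))
  sets <- list(TF1 = data.frame(target = targets,
                                mor = rep(c(1, -1, NA), length.out = 60)))
  r <- tf_target_enrichment(de1, sets, min_targets = 50, min_degs = 5)
  expect_equal(nrow(r), 1)
  expect_lt(r$p, 0.01)
  expect_gt(r$observed_fraction, r$expected_fraction)
  # mor pattern on targets[1:8]: 1,-1,NA,1,-1,NA,1,-1 ; lfc -1 x4 then +1 x4
  # concordant: activating(mor=1)&down or repressing(mor=-1)&up
  expect_equal(r$n_concordant, 4)
  expect_equal(r$n_discordant, 2)
  expect_equal(r$n_unsigned, 2)

  # below min_degs -> excluded
  de2 <- mk_de("TF2", targets[1:4], rep(-1, 4))
  r2 <- tf_target_enrichment(de2, list(TF2 = sets$TF1), min_degs = 5)
  expect_null(r2)
  # below min_targets -> excluded
  r3 <- tf_target_enrichment(de1, list(TF1 = sets$TF1[1:20, ]), min_targets = 50)
  expect_null(r3)
})

test_that("pair enrichment: degenerate reference, null, and planted overlap", {
  set.seed(130)
  universe <- sprintf("p%04d", 1:2000)
  observed <- universe[1:200]
  # reference equal to the observed set: flagged corrected OR
  r <- pair_enrichment(observed, observed, universe)
  expect_true(r$corrected)
  expect_gt(r$log_or, 5)

  # random references: OR ~ 1
  lors <- replicate(50, pair_enrichment(observed, sample(universe, 150),
                                        universe)$log_or)
  expect_lt(mean(abs(lors)), 0.25)

  # planted 3x overlap
  ref <- c(sample(observed, 60), sample(universe[201:2000], 180))
  r3 <- pair_enrichment(observed, ref, universe)
  expect_gt(r3$odds_ratio, 2)
  expect_lt(r3$p, 0.001)
})

test_that("geneset_test matches hypergeometric enumeration and extreme cases", {
  u <- sprintf("g%02d", 1:20)
  sets <- list(hit = u[1:5], miss = u[6:10])
  r <- geneset_test(u[1:5], u, sets)
  expect_equal(r$p[r$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$p[r$set == "miss"], 1)

  set.seed(140)
  for (i in 1:20) {
    q <- sample(u, sample(3:8, 1))
    s <- sample(u, sample(3:10, 1))
    r <- geneset_test(q, u, list(s = s))
    k <- length(intersect(q, s))
    expect_equal(r$p, hyper_upper_oracle(k, length(s), 20 - length(s),
                                         length(q)), tolerance = 1e-9)
  }
  expect_error(geneset_test(c(u[1], "not_in_universe"), u, sets),
               class = "crecascade_integrity_error")
})

test_that("null gene sets are enriched at about the nominal rate", {
  set.seed(141)
  u <- sprintf("g%04d", 1:500)
  hits <- replicate(400, {
    q <- sample(u, 40)
    s <- sample(u, 30)
    k <- length(intersect(q, s))
    phyper(k - 1, 30, 470, 40, lower.tail = FALSE) < 0.05
  })
  expect_lt(mean(hits), 0.09)  # discrete p-values make the test conservative
})

test_that("BH adjustment equals the step-up oracle on random p-vectors", {
  set.seed(142)
  for (i in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  links <- data.frame(cre_id = sprintf("c%d", 1:50), gene_id = sprintf("g%d", 1:50),
                      significant = rep(c(TRUE, FALSE), 25),
                      prediction_sources = "x", stringsAsFactors = FALSE)
  set.seed(143)
  cats <- lapply(1:8, function(i)
    links[sample(50, 20), c("cre_id", "gene_id")])
  names(cats) <- paste0("cat", 1:8)
  r <- eqtl_enrichment(links, cats)
  expect_equal(r$adj_p, bh_oracle(r$p), tolerance = 1e-12)
})
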