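# Independent brute-force oracles used across tests. These deliberately use
# naive loops / direct combinatorics, not the package's code paths.

# Benjamini-Hochberg step-up, textbook form
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Fisher exact p by full enumeration over tables with fixed margins
fisher_enum_oracle <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1), numeric(1))
  p_obs <- prob[ks == a]
  switch(alternative,
         two.sided = sum(prob[prob <= p_obs * (1 + 1e-7)]),
         greater = sum(prob[ks >= a]),
         less = sum(prob[ks <= a]))
}

# hypergeometric upper tail P(X >= k) from binomial coefficients
hyper_upper_oracle <- function(k, n_white, n_black, n_draw) {
  ks <- k:min(n_white, n_draw)
  if (k > min(n_white, n_draw)) return(0)
  sum(vapply(ks, function(x)
    choose(n_white, x) * choose(n_black, n_draw - x) /
      choose(n_white + n_black, n_draw), numeric(1)))
}

# O(n*m) interval-arithmetic classification of CRE context and class
classify_oracle <- function(cres, ann, w = 1500) {
  ctx <- character(nrow(cres))
  for (i in seq_len(nrow(cres))) {
    s <- cres$start[i]; e <- cres$end[i]; ch <- cres$chrom[i]
    cen <- floor((s + e) / 2)
    prom <- FALSE; intra <- FALSE
    for (g in seq_len(nrow(ann))) {
      if (ann$chrom[g] != ch) next
      if (s < ann$tss[g] + w && e > ann$tss[g] - w) prom <- TRUE
      if (cen >= ann$body_start[g] && cen < ann$body_end[g]) intra <- TRUE
    }
    ctx[i] <- if (prom) "promoter" else if (intra) "intragenic" else "intergenic"
  }
  ctx
}

interaction_class_oracle <- function(ctx, distance, w = 1500) {
  out <- character(length(ctx))
  for (i in seq_along(ctx)) {
    pos <- if (ctx[i] != "intergenic" && distance[i] < w) "proximal" else "distal"
    out[i] <- paste(ctx[i], pos, sep = "-")
  }
  out
}

# mediation filter as an explicit set difference
mediation_oracle <- function(links) {
  blocked <- unique(links$cre_id[links$significant & links$position == "proximal"])
  distal_rows <- which(links$position == "distal")
  setdiff(distal_rows, which(links$cre_id %in% blocked))
}

# layered two-hop BFS over a thresholded edge relation
bfs_layers_oracle <- function(seeds, edges_from, edges_to) {
  hop1 <- character(0)
  for (s in seeds) hop1 <- union(hop1, edges_to[edges_from == s])
  hop1 <- setdiff(hop1, seeds)
  hop2 <- character(0)
  for (s in hop1) hop2 <- union(hop2, edges_to[edges_from == s])
  hop2 <- setdiff(hop2, union(seeds, hop1))
  list(hop1 = sort(hop1), hop2 = sort(hop2))
}

# direct median-of-ratios formula
size_factor_oracle <- function(mat) {
  geo <- exp(rowMeans(log(mat)))
  ok <- is.finite(geo) & geo > 0
  sf <- apply(mat, 2, function(col) median(col[ok] / geo[ok]))
  sf / exp(mean(log(sf)))
}
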