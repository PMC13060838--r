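#' Pseudobulk aggregation of a single-cell screen
#'
#' Sums UMI counts within (perturbation x donor) groups. Aggregation is
#' exact: every retained cell's counts contribute to exactly one column.
#'
#' @param dataset filtered `screen_dataset` (each cell uniquely assigned).
#' @param min_cells_per_group groups below this size are dropped with a
#'   warning.
#' @return `pseudobulk_matrix`: list with `counts` (genes x groups) and
#'   `coldata` (group, perturbation, donor, n_cells).
#' @export
pseudobulk <- function(dataset, min_cells_per_group = 10) {
  counts <- dataset$counts
  asn <- dataset$assignments
  target <- asn$target_id[match(colnames(counts), asn$cell_id)]
  if (anyNA(target)) stop_integrity("cells without resolved assignment in pseudobulk input")
  donor <- dataset$cells$donor
  grp <- paste(target, donor, sep = "|")
  glev <- unique(grp)
  gi <- match(grp, glev)
  M <- Matrix::sparseMatrix(i = seq_along(gi), j = gi, x = 1,
                            dims = c(length(gi), length(glev)))
  pb <- as.matrix(counts %*% M)
  colnames(pb) <- glev
  n_cells <- as.integer(table(factor(grp, levels = glev)))
  coldata <- data.frame(
    group = glev,
    perturbation = sub("\\|[^|]*$", "", glev),
    donor = sub("^.*\\|", "", glev),
    n_cells = n_cells, stringsAsFactors = FALSE)
  keep <- coldata$n_cells >= min_cells_per_group
  if (!all(keep))
    warning(sprintf("dropping %d pseudobulk group(s) below %d cells",
                    sum(!keep), min_cells_per_group))
  structure(list(counts = pb[, keep, drop = FALSE],
                 coldata = coldata[keep, , drop = FALSE]),
            class = "pseudobulk_matrix")
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: per column, the median over genes with
#' all-positive counts of the ratio to the gene's geometric mean, rescaled
#' so the factors have geometric mean 1. Falls back to library-size ratios
#' (with a warning) when no gene is positive in every column.
#'
#' @param counts genes x columns count matrix (or a `pseudobulk_matrix`).
#' @return positive numeric vector, one factor per column.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "pseudobulk_matrix")) counts <- counts$counts
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no gene with nonzero counts in all columns; using library-size ratios")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf[sf > 0])))
    return(sf)
  }
  geo <- exp(loggeo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    stats::median(cnt / geo))
  sf / exp(mean(log(sf)))
}

# Log-link IRLS with an arbitrary variance function V(mu) per observation.
# Returns the coefficient vector and (X' W X)^-1 with W = mu^2 / V(mu).
.irls_fit <- function(X, y, offset, var_fun, maxit = 50, tol = 1e-9) {
  eta <- log(pmax(y, 0.5)) - offset
  beta_old <- rep(Inf, ncol(X))
  conv <- FALSE
  XtWX <- NULL
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta + offset)
    V <- var_fun(mu)
    W <- mu^2 / V
    z <- eta + (y - mu) / mu
    XtWX <- crossprod(X, X * W)
    beta <- tryCatch(solve(XtWX, crossprod(X, W * z)),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(converged = FALSE))
    eta <- drop(X %*% beta)
    if (max(abs(beta - beta_old)) < tol * (1 + max(abs(beta)))) { conv <- TRUE; break }
    beta_old <- beta
  }
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  mu <- exp(pmin(pmax(eta, -30), 30) + offset)
  list(coef = drop(beta), cov = cov, mu = mu, converged = conv || it == maxit)
}

# cell-level NB dispersion by Pearson chi-square matching: the variance of a
# column summing n_c cells is mu_c + (alpha/n_c) mu_c^2, and alpha is chosen
# so that sum (y-mu)^2 / V(mu) equals the residual degrees of freedom
.alpha_pearson <- function(y, mu, n_cells, p, upper = 50) {
  df <- max(length(y) - p, 1)
  pear <- function(a) sum((y - mu)^2 / (mu + (a / n_cells) * mu^2)) - df
  if (!is.finite(pear(0))) return(NA_real_)
  if (pear(0) <= 0) return(0)
  if (pear(upper) >= 0) return(upper)
  stats::uniroot(pear, c(0, upper), tol = 1e-6)$root
}

# mean-dispersion trend alpha(mu) = a0 + a1/mu fitted over genes
.dispersion_trend <- function(alpha, mubar) {
  ok <- is.finite(alpha) & is.finite(mubar) & mubar > 0.5
  if (sum(ok) < 10) return(c(a0 = 1e-4, a1 = 1))
  a <- pmax(alpha[ok], 1e-8); m <- mubar[ok]
  for (it in 1:2) {
    fit <- stats::lm(a ~ I(1 / m))
    a0 <- max(unname(stats::coef(fit)[1]), 0)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
    pred <- a0 + a1 / m
    keep <- a < 10 * pred + 1e-6
    if (all(keep) || sum(keep) < 10) break
    a <- a[keep]; m <- m[keep]
  }
  if (a0 == 0 && a1 == 0) a0 <- 1e-8
  c(a0 = a0, a1 = a1)
}

#' Pseudobulk negative-binomial Wald differential expression
#'
#' Per (perturbation, gene): an NB log-link GLM of pseudobulk counts on
#' perturbation + donor with log size-factor offsets. The variance model is
#' cell-count aware: a column summing `n_c` cells of cell-level NB
#' dispersion alpha has variance `mu + (alpha / n_c) mu^2`, so small
#' perturbation groups are not underdispersed relative to a large control
#' pool. Gene-wise cell-level dispersion is estimated by method-of-moments
#' around a Poisson pilot fit, shrunk toward a fitted mean-dispersion trend
#' `a0 + a1/mu` by a weighted average (`shrink_weight` on the trend), then
#' the Wald z on the perturbation coefficient gives a two-sided p. BH
#' adjustment is applied per perturbation across its tested genes; genes
#' whose fit fails are flagged and excluded from the BH denominator.
#'
#' @param pb a `pseudobulk_matrix`.
#' @param control perturbation label of the control pool
#'   (default "non-targeting").
#' @param tested_genes NULL (all genes for every perturbation), a character
#'   vector (same genes for every perturbation), or a named list mapping
#'   perturbation to its tested gene panel.
#' @param shrink_weight weight on the dispersion trend in the weighted
#'   average (default 0.75).
#' @param perturbations subset of perturbations to test (default all
#'   non-control).
#' @return `de_result` data.frame: perturbation, response_gene, log2fc, se,
#'   wald_p, adj_p, n_pseudobulk_columns.
#' @export
nb_wald <- function(pb, control = "non-targeting", tested_genes = NULL,
                    shrink_weight = 0.75, perturbations = NULL) {
  cd <- pb$coldata
  Y <- pb$counts
  sf <- size_factors(Y)
  perts <- perturbations %||% setdiff(unique(cd$perturbation), control)
  ctrl_cols <- which(cd$perturbation == control)
  if (!length(ctrl_cols)) stop_integrity("control pool '%s' absent from pseudobulk", control)

  panel_of <- function(p) {
    if (is.null(tested_genes)) rownames(Y)
    else if (is.list(tested_genes)) tested_genes[[p]] %||% character(0)
    else tested_genes
  }

  # dataset-wide gene dispersion: one fit per gene over all columns with the
  # full donor + perturbation design, so dozens of residual df inform each
  # gene-wise estimate before trend shrinkage
  all_genes <- unique(unlist(lapply(perts, panel_of), use.names = FALSE))
  all_genes <- intersect(all_genes, rownames(Y))
  donor_all <- factor(cd$donor)
  pert_all <- factor(cd$perturbation)
  X_full <- if (nlevels(pert_all) > 1 && nlevels(donor_all) > 1)
    stats::model.matrix(~ donor_all + pert_all)
  else if (nlevels(pert_all) > 1) stats::model.matrix(~ pert_all)
  else if (nlevels(donor_all) > 1) stats::model.matrix(~ donor_all)
  else matrix(1, ncol(Y), 1)
  off_all <- log(sf)
  n_all <- cd$n_cells
  mubar_cell <- rowMeans(sweep(Y[all_genes, , drop = FALSE], 2, n_all, "/"))
  alpha_raw <- rep(NA_real_, length(all_genes))
  names(alpha_raw) <- all_genes
  for (g in seq_along(all_genes)) {
    y <- Y[all_genes[g], ]
    if (all(y == 0)) next
    f <- .irls_fit(X_full, y, off_all, function(mu) mu)  # Poisson pilot fit
    if (!isTRUE(f$converged)) next
    alpha_raw[g] <- .alpha_pearson(y, f$mu, n_all, ncol(X_full))
  }
  tr <- .dispersion_trend(alpha_raw, mubar_cell)
  alpha_use <- shrink_weight * (tr["a0"] + tr["a1"] / pmax(mubar_cell, 1e-8)) +
    (1 - shrink_weight) * pmax(alpha_raw, 0)
  alpha_use <- pmin(pmax(alpha_use, 1e-8), 50)
  names(alpha_use) <- all_genes

  out <- vector("list", length(perts))
  for (pi in seq_along(perts)) {
    pert <- perts[pi]
    pcols <- which(cd$perturbation == pert)
    if (length(pcols) < 2) next
    cols <- c(pcols, ctrl_cols)
    genes <- intersect(panel_of(pert), rownames(Y))
    if (!length(genes)) next
    Ys <- Y[genes, cols, drop = FALSE]
    off <- log(sf[cols])
    donor <- factor(cd$donor[cols])
    is_pert <- as.numeric(cd$perturbation[cols] == pert)
    X <- if (nlevels(donor) > 1)
      stats::model.matrix(~ donor + is_pert)
    else stats::model.matrix(~ is_pert)
    bcol <- ncol(X)
    n_cells <- cd$n_cells[cols]

    log2fc <- se <- wald_p <- rep(NA_real_, length(genes))
    for (g in seq_along(genes)) {
      y <- Ys[g, ]
      a <- alpha_use[genes[g]]
      if (all(y == 0) || is.na(a)) next
      f <- .irls_fit(X, y, off, function(mu) mu + (a / n_cells) * mu^2)
      if (is.null(f$cov) || !isTRUE(f$converged)) next
      b <- f$coef[bcol]; s <- sqrt(f$cov[bcol, bcol])
      if (!is.finite(b) || !is.finite(s) || s <= 0) next
      log2fc[g] <- b / log(2)
      se[g] <- s / log(2)
      wald_p[g] <- 2 * stats::pnorm(-abs(b / s))
    }
    adj_p <- rep(NA_real_, length(genes))
    ok <- !is.na(wald_p)
    adj_p[ok] <- stats::p.adjust(wald_p[ok], method = "BH")
    out[[pi]] <- data.frame(
      perturbation = pert, response_gene = genes, log2fc = log2fc, se = se,
      wald_p = wald_p, adj_p = adj_p,
      n_pseudobulk_columns = length(cols), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(perturbation = character(),
                                      response_gene = character(), log2fc = numeric(),
                                      se = numeric(), wald_p = numeric(),
                                      adj_p = numeric(), n_pseudobulk_columns = integer())
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Variable-gene selection for the promoter-screen response universe
#'
#' Ranks genes by excess coefficient of variation relative to the median in
#' log-mean bins of normalized pseudobulk expression and keeps the top N.
#'
#' @param pb a `pseudobulk_matrix`.
#' @param n number of variable genes to keep.
#' @return character vector of gene ids.
#' @export
variable_genes <- function(pb, n = 2000L) {
  Y <- sweep(pb$counts, 2, size_factors(pb), "/")
  m <- rowMeans(Y)
  v <- apply(Y, 1, stats::var)
  ok <- m > 0 & v > 0
  cv2 <- rep(NA_real_, nrow(Y)); cv2[ok] <- v[ok] / m[ok]^2
  bins <- cut(log10(m[ok]), breaks = 20)
  med <- stats::ave(cv2[ok], bins, FUN = function(x) stats::median(x, na.rm = TRUE))
  score <- rep(-Inf, nrow(Y))
  score[ok] <- log(cv2[ok] / pmax(med, 1e-12))
  rownames(pb$counts)[order(score, decreasing = TRUE)][seq_len(min(n, sum(ok)))]
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d perturbation x gene tests (%d perturbations)\n",
              nrow(x), length(unique(x$perturbation))))
  cat(sprintf("  significant at adj_p < 0.1: %d\n",
              sum(!is.na(x$adj_p) & x$adj_p < 0.1)))
  invisible(x)
}

#' @export
summary.de_result <- function(object, fdr = 0.1, ...) {
  sig <- !is.na(object$adj_p) & object$adj_p < fdr
  data.frame(
    n_tests = nrow(object),
    n_perturbations = length(unique(object$perturbation)),
    n_significant = sum(sig),
    n_failed = sum(is.na(object$wald_p)),
    median_abs_log2fc_sig = stats::median(abs(object$log2fc[sig])))
}
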