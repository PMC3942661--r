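#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median over genes of the ratio
#' of its count to the across-library geometric mean of that gene, taken
#' over genes with nonzero counts in every library.
#'
#' @param counts Genes x libraries integer matrix (or a `count_matrix`).
#' @return Named per-library size factors, all `> 0`.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (ncol(counts) < 2) stopf("need at least 2 libraries")
  use <- rowSums(counts == 0) == 0
  if (!any(use)) stopf("no gene has nonzero counts in all libraries")
  lg <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  if (any(sf <= 0)) stopf("non-positive size factor")
  sf
}

#' Per-gene NB dispersion with a mean trend
#'
#' Method-of-moments gene-wise estimates
#' `alpha_g = max(0, (s2_g - mu_g) / mu_g^2)` from normalized counts, with
#' variances pooled within groups, plus a smooth mean-dispersion trend from
#' a robust linear fit of `log(alpha)` on `log(mu)`. The working dispersion
#' is the maximum of the gene-wise estimate and the trend — the
#' conservative choice for small replicate numbers.
#'
#' @param norm_counts Genes x libraries matrix of counts already divided by
#'   size factors.
#' @param groups Character/factor of length `ncol(norm_counts)`.
#' @return Data frame `mean`, `alpha_mom`, `alpha_trend`, `alpha_working`;
#'   all-zero genes get `NA` (excluded from testing downstream).
#' @export
estimate_dispersion <- function(norm_counts, groups) {
  groups <- as.character(groups)
  if (max(table(groups)) < 2) stopf("need >= 2 replicates in some group")
  mu <- rowMeans(norm_counts)
  grp <- unique(groups)
  ss <- matrix(0, nrow(norm_counts), 2)  # sum of (n_k-1)*s2_k, dof
  for (g in grp) {
    cols <- groups == g
    if (sum(cols) < 2) next
    v <- apply(norm_counts[, cols, drop = FALSE], 1, var)
    ss[, 1] <- ss[, 1] + (sum(cols) - 1) * v
    ss[, 2] <- ss[, 2] + (sum(cols) - 1)
  }
  s2 <- ss[, 1] / ss[, 2]
  alpha <- pmax(0, (s2 - mu) / mu^2)
  alpha[mu == 0] <- NA_real_
  fit_ok <- which(!is.na(alpha) & alpha > 0 & mu > 0)
  trend <- rep(NA_real_, length(mu))
  if (length(fit_ok) >= 10) {
    fit <- tryCatch(MASS::rlm(log(alpha[fit_ok]) ~ log(mu[fit_ok]), maxit = 50),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      fit <- lm(log(alpha[fit_ok]) ~ log(mu[fit_ok]))
    co <- stats::coef(fit)
    trend[mu > 0] <- exp(co[1] + co[2] * log(mu[mu > 0]))
  } else if (length(fit_ok) > 0) {
    trend[mu > 0] <- median(alpha[fit_ok])
  } else {
    trend[mu > 0] <- 0
  }
  data.frame(mean = mu, alpha_mom = alpha, alpha_trend = trend,
             alpha_working = pmax(alpha, trend),
             row.names = rownames(norm_counts))
}

#' Negative-binomial two-group differential expression (Wald test)
#'
#' Per gene, group means of normalized counts are compared on the log
#' scale with a Wald statistic whose variance follows the NB model
#' `Var(K) = mu + alpha * mu^2` with the working dispersion from
#' [estimate_dispersion()], followed by Benjamini-Hochberg adjustment.
#' Genes with zero counts in all libraries are excluded from testing.
#'
#' @param counts Genes x libraries integer matrix or `count_matrix`.
#' @param groups Two-level character/factor over libraries; the fold change
#'   is second level versus first (levels in order of first appearance).
#' @param sf Optional size factors (computed when `NULL`).
#' @param dispersions Optional working dispersion vector; estimated when
#'   `NULL`. Required (as `pooled_alpha`) when either group has a single
#'   replicate.
#' @param pooled_alpha Optional scalar dispersion override enabling
#'   single-replicate designs.
#' @return A data.frame of class `nb_de`: `gene`, `baseMeanA`, `baseMeanB`,
#'   `foldChange`, `log2FoldChange`, `dispersion`, `stat`, `pvalue`,
#'   `padj`, with groups and size factors as attributes.
#' @export
nb_test <- function(counts, groups, sf = NULL, dispersions = NULL,
                    pooled_alpha = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (missing(groups)) groups <- counts$libraries$group
    counts <- counts$counts
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stopf("exactly two groups required, got %d", length(lev))
  nA <- sum(groups == lev[1]); nB <- sum(groups == lev[2])
  if ((nA < 2 || nB < 2) && is.null(pooled_alpha) && is.null(dispersions))
    stopf("single-replicate group: supply pooled_alpha to proceed")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (is.null(dispersions)) {
    dispersions <- if (!is.null(pooled_alpha))
      rep(pooled_alpha, nrow(counts))
    else estimate_dispersion(norm, groups)$alpha_working
  }
  A <- groups == lev[1]; B <- groups == lev[2]
  qA <- rowMeans(norm[, A, drop = FALSE])
  qB <- rowMeans(norm[, B, drop = FALSE])
  alpha <- dispersions
  # Var(qhat_k) = (1/n_k^2) * sum_j (q/s_j + alpha q^2) on the common scale
  vA <- (qA * sum(1 / sf[A]) + alpha * qA^2 * nA) / nA^2
  vB <- (qB * sum(1 / sf[B]) + alpha * qB^2 * nB) / nB^2
  eps <- 0.5 * mean(1 / sf)      # continuity for zero group means
  qA2 <- qA + eps; qB2 <- qB + eps
  stat <- (log(qB2) - log(qA2)) / sqrt(vA / qA2^2 + vB / qB2^2)
  tested <- qA + qB > 0 & !is.na(alpha)
  pvalue <- ifelse(tested, 2 * pnorm(-abs(stat)), NA_real_)
  pvalue <- pmin(pvalue, 1)
  padj <- rep(NA_real_, length(pvalue))
  padj[tested] <- p.adjust(pvalue[tested], method = "BH")
  res <- data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                    baseMeanA = qA, baseMeanB = qB,
                    foldChange = qB2 / qA2,
                    log2FoldChange = log2(qB2 / qA2),
                    dispersion = alpha, stat = stat,
                    pvalue = pvalue, padj = padj,
                    stringsAsFactors = FALSE)
  rownames(res) <- res$gene
  attr(res, "groups") <- lev
  attr(res, "size_factors") <- sf
  class(res) <- c("nb_de", "data.frame")
  res
}

#' @export
print.nb_de <- function(x, ...) {
  lev <- attr(x, "groups")
  cat(sprintf("NB differential expression: %s vs %s, %d genes tested\n",
              lev[2], lev[1], sum(!is.na(x$pvalue))))
  sig <- !is.na(x$padj) & x$padj < 0.05
  cat(sprintf("  significant at adjusted p < 0.05: %d (%d up, %d down)\n",
              sum(sig), sum(sig & x$log2FoldChange > 0),
              sum(sig & x$log2FoldChange < 0)))
  print(utils::head(as.data.frame(x)[order(x$padj), ], 6))
  invisible(x)
}

#' @export
summary.nb_de <- function(object, alpha = 0.05, ...) {
  sig <- !is.na(object$padj) & object$padj < alpha
  out <- list(n_tested = sum(!is.na(object$pvalue)),
              n_significant = sum(sig),
              n_up = sum(sig & object$log2FoldChange > 0),
              n_down = sum(sig & object$log2FoldChange < 0),
              alpha = alpha)
  class(out) <- "summary.nb_de"
  out
}

#' @export
print.summary.nb_de <- function(x, ...) {
  cat(sprintf("%d genes tested; %d significant at adjusted p < %g (%d up, %d down)\n",
              x$n_tested, x$n_significant, x$alpha, x$n_up, x$n_down))
  invisible(x)
}

#' Variance-reducing log transform of normalized counts
#'
#' `log2(count / size_factor + 1)` per cell: a simple monotone transform
#' that tames the count-variance mean dependence for clustering,
#' correlation and PCA diagnostics.
#'
#' @param counts Genes x libraries matrix or `count_matrix`.
#' @param sf Size factors (computed when `NULL`).
#' @return Transformed matrix of the same shape.
#' @export
transform_counts <- function(counts, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Between-library concordance diagnostics
#'
#' Pearson correlations between libraries on the transformed matrix, an
#' average-linkage tree on the correlation distance `1 - r`, and PCA of
#' gene-centered transformed values (first two components with
#' explained-variance fractions).
#'
#' @param mat Transformed genes x libraries matrix
#'   ([transform_counts()]).
#' @return List with `correlation` (libraries x libraries), `tree`
#'   (`hclust`), `pca` (list `scores` = libraries x 2, `var_explained`).
#'   Constant libraries yield `NA` correlations and are reported in
#'   `constant_libraries`.
#' @export
concordance <- function(mat) {
  if (ncol(mat) < 3) stopf("need at least 3 libraries")
  const <- apply(mat, 2, sd) == 0
  cc <- suppressWarnings(cor(mat))
  cc_d <- cc; cc_d[is.na(cc_d)] <- 0
  tree <- hclust(as.dist(1 - cc_d), method = "average")
  centered <- mat - rowMeans(mat)
  pc <- prcomp(t(centered), center = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(correlation = cc, tree = tree,
       pca = list(scores = scores, var_explained = ve),
       constant_libraries = colnames(mat)[const])
}
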