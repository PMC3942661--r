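test_that("size factors are median-of-ratios against a geometric reference", {
  m <- matrix(c(10, 20, 40, 80, 160,
                10, 20, 40, 80, 160), ncol = 2)
  rownames(m) <- paste0("g", 1:5)
  expect_equal(unname(size_factors(m)), c(1, 1))
  # library B exactly 2x library A -> factors proportional to (1, 2);
  # the geometric reference makes them (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10, 20, 40, 80, 160), B = 2 * c(10, 20, 40, 80, 160))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # invariant to gene order
  expect_equal(unname(size_factors(m2[c(3, 1, 5, 2, 4), ])), unname(sf))
  # needs one gene nonzero everywhere
  m3 <- cbind(c(5, 0), c(0, 7))
  expect_error(size_factors(m3), "nonzero")
  # median-ratio invariant: after normalization the median ratio to the
  # pseudo-reference is 1
  cm <- tq_counts()$counts
  sf4 <- size_factors(cm)
  use <- rowSums(cm == 0) == 0
  ref <- exp(rowMeans(log(cm[use, ])))          # geometric pseudo-reference
  norm <- sweep(cm[use, ], 2, sf4, "/")
  # median log-ratio of each normalized library to the reference is 0
  expect_equal(unname(apply(log(norm / ref), 2, median)), rep(0, ncol(cm)),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  cm <- tq_counts()$counts
  cm <- cm[rowSums(cm) > 0, ]
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cm)),
               tolerance = 1e-10)
})

test_that("dispersion estimation clamps, pools and recovers the truth", {
  # constant counts within groups -> moment estimate clamps to 0
  m <- matrix(50, nrow = 3, ncol = 6, dimnames = list(paste0("g", 1:3), NULL))
  d <- estimate_dispersion(m, rep(c("A", "B"), each = 3))
  expect_true(all(d$alpha_mom == 0))
  # Poisson data: median working dispersion shrinks toward 0 with replicates
  set.seed(4)
  mp <- matrix(rpois(800 * 10, lambda = rep(exp(runif(800, 4, 8)), 10)), 800)
  dp <- estimate_dispersion(mp, rep(c("A", "B"), each = 5))
  expect_lt(median(dp$alpha_working), 0.02)
  # alpha = 0.1 across means 100..10,000: trend recovers within 30%
  set.seed(5)
  mu <- exp(runif(1500, log(100), log(10000)))
  mn <- matrix(rnbinom(1500 * 6, mu = rep(mu, 6), size = 10), 1500)
  dn <- estimate_dispersion(mn, rep(c("A", "B"), each = 3))
  expect_lt(abs(median(dn$alpha_trend) - 0.1), 0.03)
  # all-zero genes are excluded from testing
  mz <- rbind(mp[1:5, ], 0)
  dz <- estimate_dispersion(mz, rep(c("A", "B"), each = 5))
  expect_true(is.na(dz$alpha_mom[6]))
  expect_error(estimate_dispersion(m[, 1, drop = FALSE], "A"), "replicates")
})

test_that("NB Wald test behaves at the identity and detects real changes", {
  set.seed(6)
  groups <- rep(c("A", "B"), each = 3)
  base <- matrix(rnbinom(300 * 6, mu = rep(exp(runif(300, 4, 8)), 6),
                         size = 20), 300,
                 dimnames = list(paste0("g", 1:300), NULL))
  # identical count vectors in both groups -> fold change 1, p = 1
  m <- base; m[1, ] <- rep(c(40, 55, 70), 2)
  res <- nb_test(m, groups, sf = rep(1, 6))
  expect_equal(res$foldChange[1], 1)
  expect_equal(res$pvalue[1], 1)
  # a strong true change is found with a small adjusted p
  m2 <- base
  m2[2, ] <- rnbinom(6, mu = rep(c(300, 2400), each = 3), size = 20)
  res2 <- nb_test(m2, groups)
  expect_lt(res2$padj[2], 0.01)
  expect_gt(res2$log2FoldChange[2], 1.5)
  # single-replicate groups are refused without an override
  expect_error(nb_test(m[, c(1, 4), drop = FALSE], c("A", "B")),
               "single-replicate")
  expect_s3_class(nb_test(m[, c(1, 4), drop = FALSE], c("A", "B"),
                          pooled_alpha = 0.1), "nb_de")
  # BH adjustment is monotone in raw-p rank and padj >= p
  ok <- !is.na(res2$pvalue)
  o <- order(res2$pvalue[ok])
  expect_true(all(diff(res2$padj[ok][o]) >= -1e-12))
  expect_true(all(res2$padj[ok] >= res2$pvalue[ok] - 1e-12))
})

test_that("transformed counts are monotone and size-factor stable", {
  m <- cbind(A = c(0, 4, 10, 100), B = c(0, 8, 20, 200))
  tr <- transform_counts(m, sf = c(1, 2))
  expect_equal(unname(tr[1, "A"]), 0)               # zero count maps to 0
  expect_equal(unname(tr[, "A"]), unname(tr[, "B"]))  # B = 2A with sf 2
  expect_true(all(diff(tr[, "A"]) > 0))
})

test_that("concordance reports correlations, tree and PCA structure", {
  cm <- tq_counts()
  tr <- transform_counts(cm$counts[rowSums(cm$counts) > 0, ])
  cc <- concordance(tr)
  expect_equal(diag(cc$correlation), rep(1, ncol(tr)), ignore_attr = TRUE)
  # a duplicated library correlates perfectly and joins at height ~0
  tr2 <- cbind(tr, dup = tr[, 1])
  cc2 <- concordance(tr2)
  expect_equal(cc2$correlation[1, "dup"], 1)
  h <- cc2$tree$height[which.min(cc2$tree$height)]
  expect_lt(h, 1e-12)
  # explained variance fractions are sane
  expect_true(all(cc2$pca$var_explained >= 0 &
                    cc2$pca$var_explained <= 1))
  # constant libraries are reported
  tr3 <- cbind(tr, flat = rep(1, nrow(tr)))
  expect_identical(suppressWarnings(concordance(tr3))$constant_libraries,
                   "flat")
  expect_error(concordance(tr[, 1:2]), "3 libraries")
})

test_that("knockdown libraries separate from controls in PCA", {
  cfg <- simulation_config(n_genes = 60, library_size = 30000, seed = 17)
  cm <- simulate_counts_matrix(cfg)
  tr <- transform_counts(cm$counts[rowSums(cm$counts) > 0, ])
  cc <- concordance(tr)
  sil <- tissueqc:::group_silhouette(cc$pca$scores, cm$libraries$group)
  expect_gt(sil, 0)
})

test_that("the number of DE genes does not grow with contamination", {
  de_n <- vapply(c(0, 0.3, 0.6), function(cc) {
    libs <- sim_libraries(n_wt = 5, n_kd = 5, cdna_input = 4)
    libs$contamination <- cc
    sum(vapply(c(23, 24), function(s) {
      cfg <- simulation_config(n_genes = 60, library_size = 30000,
                               seed = s, libraries = libs)
      cm <- simulate_counts_matrix(cfg)
      res <- nb_test(cm$counts[rowSums(cm$counts) > 0, ],
                     cm$libraries$group)
      sum(res$padj < 0.05, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(de_n) <= 0))
  expect_gt(de_n[1], 0)
})
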