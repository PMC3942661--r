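#' Tissue-expression class sets
#'
#' Named gene-id sets (`neuronal`, `glial`, `ubiquitous`) used to classify
#' differentially expressed genes. Genes appearing in more than one class
#' are dropped from all of them (classification must be disjoint); the
#' number dropped is recorded.
#'
#' @param neuronal,glial,ubiquitous Character vectors of gene ids.
#' @return Object of class `tissue_class_sets`, with attribute
#'   `n_deoverlapped`.
#' @export
tissue_class_sets <- function(neuronal, glial, ubiquitous) {
  all <- c(neuronal, glial, ubiquitous)
  dup <- unique(all[duplicated(all)])
  out <- list(neuronal = setdiff(unique(neuronal), dup),
              glial = setdiff(unique(glial), dup),
              ubiquitous = setdiff(unique(ubiquitous), dup))
  structure(out, n_deoverlapped = length(dup), class = "tissue_class_sets")
}

#' Classify a DE gene list by tissue-expression class
#'
#' Exact set intersections with each class, with percentages of the DE
#' list size rounded half-up to one decimal — the layout of a
#' per-comparison enrichment table row.
#'
#' @param de_genes Character vector of DE gene ids (no duplicates).
#' @param classes A [tissue_class_sets()].
#' @return Data frame with one row per class: `class`, `n_class`,
#'   `n_de_in_class`, `percent`.
#' @export
classify_de <- function(de_genes, classes) {
  if (length(de_genes) == 0) stopf("empty DE list")
  if (anyDuplicated(de_genes)) stopf("duplicate ids in the DE list")
  do.call(rbind, lapply(names(classes), function(cl) {
    k <- length(intersect(de_genes, classes[[cl]]))
    data.frame(class = cl, n_class = length(classes[[cl]]),
               n_de_in_class = k,
               percent = round_half_up(100 * k / length(de_genes), 1),
               stringsAsFactors = FALSE)
  }))
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (x1 + x2)/(n1 + n2)`; `p-value = 2 * Phi(-|z|)`. Used to compare
#' the class composition of two DE lists. Degenerate pooled proportions
#' (0 or 1) return `p = 1` by convention.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return List `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stopf("invalid counts: need 0 <= x <= n, n >= 1")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Upper-tail hypergeometric overlap test
#'
#' Significance of the overlap between two gene lists drawn from a common
#' universe: `P(X >= overlap)` for `X ~ Hypergeometric(universe, size_b,
#' size_a)`, evaluated on the log scale internally for numerical range.
#'
#' @param size_a,size_b Sizes of the two lists.
#' @param overlap Observed overlap (`<= min(size_a, size_b)`).
#' @param universe Universe size (typically the genes tested for DE).
#' @return Upper-tail p-value.
#' @export
hypergeometric_overlap <- function(size_a, size_b, overlap, universe) {
  if (overlap > min(size_a, size_b) || size_a > universe ||
      size_b > universe || overlap < 0)
    stopf("inconsistent sizes for the hypergeometric test")
  if (overlap == 0) return(1)
  exp(min(0, phyper(overlap - 1, size_b, universe - size_b, size_a,
                    lower.tail = FALSE, log.p = TRUE)))
}

#' Tissue-class enrichment table for one or two comparisons
#'
#' Builds the per-comparison class breakdown ([classify_de()]) and, when
#' two DE lists are given, the pairwise two-proportion z statistics per
#' class.
#'
#' @param de_lists Named list of one or two character vectors of DE gene
#'   ids.
#' @param classes A [tissue_class_sets()].
#' @return List with `rows` (stacked [classify_de()] rows, one block per
#'   comparison) and, for two comparisons, `tests` (per class: `z`,
#'   `p_value`).
#' @export
enrichment_table <- function(de_lists, classes) {
  rows <- do.call(rbind, lapply(names(de_lists), function(nm) {
    r <- classify_de(de_lists[[nm]], classes)
    cbind(comparison = nm, n_de = length(de_lists[[nm]]), r)
  }))
  tests <- NULL
  if (length(de_lists) == 2) {
    a <- de_lists[[1]]; b <- de_lists[[2]]
    tests <- do.call(rbind, lapply(names(classes), function(cl) {
      t <- two_proportion_z(length(intersect(a, classes[[cl]])), length(a),
                            length(intersect(b, classes[[cl]])), length(b))
      data.frame(class = cl, z = t$z, p_value = t$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(rows = rows, tests = tests)
}
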