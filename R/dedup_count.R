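#' Remove PCR-duplicate read pairs
#'
#' Pairs sharing a fragment signature — reference, leftmost start,
#' rightmost end and orientation — are collapsed to a single
#' representative: the pair with the highest summed base quality, ties
#' broken by first occurrence. This is the paired-end `rmdup` signature;
#' using both fragment ends (not start only) matches whole-pair PCR
#' duplication.
#'
#' @param alignments Alignment data.frame ([read_sam()]) or a fragment
#'   table ([pair_fragments()]).
#' @return List with `fragments` (deduplicated fragment table), `kept_ids`,
#'   `duplicate_rate` (removed pairs / total pairs), `n_total`, `n_removed`
#'   and `orphans`.
#' @export
remove_duplicates <- function(alignments) {
  frag <- if (!is.null(alignments$mate)) pair_fragments(alignments) else alignments
  n <- nrow(frag)
  if (n == 0)
    return(list(fragments = frag, kept_ids = character(0),
                duplicate_rate = NA_real_, n_total = 0L, n_removed = 0L,
                orphans = attr(frag, "orphans") %||% 0L))
  sig <- paste(frag$rname, frag$start, frag$end, frag$orientation, sep = ":")
  # stable order: best summed quality first within signature, original
  # order breaking ties, then keep the first of each signature
  o <- order(sig, -frag$squal, seq_len(n))
  keep_sorted <- !duplicated(sig[o])
  keep <- logical(n)
  keep[o] <- keep_sorted
  out <- frag[keep, ]
  attr(out, "orphans") <- attr(frag, "orphans") %||% 0L
  list(fragments = out, kept_ids = out$qname,
       duplicate_rate = (n - nrow(out)) / n,
       n_total = n, n_removed = n - nrow(out),
       orphans = attr(frag, "orphans") %||% 0L)
}

#' Duplicate-rate versus cDNA-input diagnostic
#'
#' PCR duplication is driven by library complexity: the less input cDNA,
#' the more amplification and the higher the duplicate fraction. This
#' diagnostic computes the Pearson correlation of per-library duplicate
#' counts (and rates) against nominal cDNA input and raises a flag when the
#' rate-input correlation is strongly negative (`r < -0.8`), the signature
#' of an input-driven duplication problem.
#'
#' @param duplicate_rate Per-library duplicate fractions (>= 3 libraries).
#' @param cdna_input Per-library nominal input (ng).
#' @param n_total Optional per-library total pair counts, used to report
#'   duplicate counts as well as rates.
#' @return List with `table` (per-library data.frame), `r_rate`, `r_count`
#'   (Pearson correlations, `NA` when undefined) and `flag`.
#' @export
duplicate_input_diagnostic <- function(duplicate_rate, cdna_input,
                                       n_total = NULL) {
  if (length(duplicate_rate) < 3) stopf("need at least 3 libraries")
  if (length(cdna_input) != length(duplicate_rate))
    stopf("input vector length mismatch")
  counts <- if (is.null(n_total)) NULL else round(duplicate_rate * n_total)
  undef <- sd(cdna_input) == 0 || sd(duplicate_rate) == 0
  r_rate <- if (undef) NA_real_ else cor(duplicate_rate, cdna_input)
  r_count <- if (is.null(counts) || undef || sd(counts) == 0) NA_real_
             else cor(counts, cdna_input)
  tab <- data.frame(library = seq_along(duplicate_rate),
                    cdna_input = cdna_input,
                    duplicate_rate = duplicate_rate)
  if (!is.null(counts)) tab$duplicate_count <- counts
  list(table = tab, r_rate = r_rate, r_count = r_count,
       flag = isTRUE(!is.na(r_rate) && r_rate < -0.8))
}

# Exon interval index per reference for overlap queries.
exon_index <- function(annotation) {
  e <- annotation$exons
  lapply(split(e, e$ref), function(d)
    list(ir = IRanges::IRanges(d$start + 1L, d$end), gene = d$gene_id))
}

# Gene ids overlapped by a set of 0-based half-open intervals; returns a
# list "query index -> character vector of gene ids".
overlap_genes <- function(idx, rname, start, end) {
  res <- vector("list", length(start))
  for (r in unique(rname)) {
    sel <- which(rname == r)
    if (!r %in% names(idx)) stopf("unknown reference '%s'", r)
    q <- IRanges::IRanges(start[sel] + 1L, end[sel])
    hits <- IRanges::findOverlaps(q, idx[[r]]$ir)
    g <- split(idx[[r]]$gene[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits))
    res[sel[as.integer(names(g))]] <- g
  }
  res
}

#' Union-mode gene-level fragment counting
#'
#' Assigns each fragment to the union of genes whose exons overlap either
#' mate (strands ignored: unstranded protocol). A fragment whose feature
#' set has exactly one gene is counted to it; two or more genes make it
#' `ambiguous`; none make it `no_feature`; a mate mapping quality below
#' `min_mapq` makes the fragment `low_quality` before any overlap test.
#' The four categories always partition the fragment total. One pair is
#' one count.
#'
#' @param fragments Fragment table ([pair_fragments()] or
#'   [remove_duplicates()]`$fragments`), normally deduplicated.
#' @param annotation Gene models ([build_annotation()] / [read_gtf()]).
#' @param min_mapq Mapping-quality floor (default 10).
#' @return List with `counts` (named integer vector over all genes) and
#'   `tallies` (`counted`, `ambiguous`, `no_feature`, `low_quality`).
#' @export
count_union <- function(fragments, annotation, min_mapq = 10) {
  genes <- annotation$genes$gene_id
  counts <- stats::setNames(integer(length(genes)), genes)
  n <- nrow(fragments)
  tallies <- c(counted = 0L, ambiguous = 0L, no_feature = 0L, low_quality = 0L)
  if (n == 0) return(list(counts = counts, tallies = tallies))
  lowq <- fragments$mapq_min < min_mapq
  idx <- exon_index(annotation)
  ok <- which(!lowq)
  hit1 <- overlap_genes(idx, fragments$rname[ok], fragments$start1[ok],
                        fragments$end1[ok])
  hit2 <- overlap_genes(idx, fragments$rname[ok], fragments$start2[ok],
                        fragments$end2[ok])
  nun <- integer(length(ok))
  assigned <- character(length(ok))
  for (i in seq_along(ok)) {
    g <- unique(c(hit1[[i]], hit2[[i]]))
    nun[i] <- length(g)
    if (length(g) == 1L) assigned[i] <- g
  }
  tab <- table(factor(assigned[nun == 1L], levels = genes))
  counts[] <- as.integer(tab)
  tallies["counted"] <- sum(nun == 1L)
  tallies["ambiguous"] <- sum(nun >= 2L)
  tallies["no_feature"] <- sum(nun == 0L)
  tallies["low_quality"] <- sum(lowq)
  stopifnot(sum(tallies) == n)
  list(counts = counts, tallies = tallies)
}

#' FPKM normalization
#'
#' `FPKM_g = counts_g / (union-exon length_g [kb] * counted_total
#' [millions])`. The denominator is the number of fragments counted to
#' genes, not raw mapped reads.
#'
#' @param counts Named per-gene fragment counts.
#' @param annotation Gene models (for union-exon lengths), or a named
#'   numeric vector of lengths in bp.
#' @param counted_total Total fragments counted to genes (> 0); defaults to
#'   `sum(counts)`.
#' @return Named per-gene FPKM vector.
#' @export
fpkm <- function(counts, annotation, counted_total = sum(counts)) {
  if (counted_total <= 0) stopf("counted_total must be > 0")
  len <- if (inherits(annotation, "annotation"))
    stats::setNames(annotation$genes$union_length, annotation$genes$gene_id)[names(counts)]
  else annotation[names(counts)]
  if (anyNA(len)) stopf("missing union-exon length for some genes")
  if (any(len <= 0)) stopf("zero-length gene model")
  counts / ((len / 1e3) * (counted_total / 1e6))
}
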