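#' Read-pair quality filter thresholds
#'
#' Defaults follow the standard stringent recipe: any unknown nucleotide
#' drops the pair, a single-base run of 50 nt or longer drops it, and so
#' does a per-mate mean Phred score strictly below 30. `trim5` bases are
#' removed from each mate's 5' end *before* filtering.
#'
#' @param max_n Allowed 'N' bases per mate (default 0: one 'N' drops).
#' @param homopolymer_min Minimal homopolymer run length that drops a mate.
#' @param mean_phred_min Minimal per-mate mean Phred score (strictly-below
#'   fails, so a mate averaging exactly the threshold is kept).
#' @param trim5 Bases trimmed from each mate's 5' end before filtering.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_n = 0, homopolymer_min = 50,
                              mean_phred_min = 30, trim5 = 0) {
  if (homopolymer_min < 1) stopf("homopolymer_min must be >= 1")
  if (trim5 < 0) stopf("trim5 must be >= 0")
  structure(list(max_n = as.integer(max_n),
                 homopolymer_min = as.integer(homopolymer_min),
                 mean_phred_min = mean_phred_min,
                 trim5 = as.integer(trim5)),
            class = "filter_thresholds")
}

# Vectorized per-mate statistics.
mate_n_count <- function(seqs) {
  nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
}
mate_has_homopolymer <- function(seqs, min_run) {
  grepl(sprintf("([ACGT])\\1{%d,}", min_run - 1L), seqs, perl = TRUE)
}
mate_mean_phred <- function(quals) {
  vapply(quals, function(q) {
    if (nchar(q) == 0) return(-Inf)  # empty mate: forced low-quality drop
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter read pairs on unknown bases, homopolymers and mean quality
#'
#' A pair is dropped when *either* mate fails *any* rule; the first failing
#' rule in the order unknown-nucleotide, homopolymer, low-quality is
#' reported. The homopolymer rule looks for a maximal run of one identical
#' base (N never extends a run) of length `>= homopolymer_min` anywhere in
#' the mate; the quality rule uses the arithmetic mean Phred over all bases
#' of a mate. When `thresholds$trim5 > 0` the pairs are trimmed first (see
#' [trim_five_prime()]).
#'
#' @param reads Data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param thresholds A [filter_thresholds()].
#' @return A data.frame `id`, `verdict` (`"keep"` or `"drop"`), `reason`
#'   (`NA`, `"unknown_nt"`, `"homopolymer"`, `"low_quality"`), with the
#'   trimmed reads attached as attribute `reads`.
#' @export
filter_read_pairs <- function(reads, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (thresholds$trim5 > 0) reads <- trim_five_prime(reads, thresholds$trim5)
  n_bad <- mate_n_count(reads$seq1) > thresholds$max_n |
    mate_n_count(reads$seq2) > thresholds$max_n
  hp_bad <- mate_has_homopolymer(reads$seq1, thresholds$homopolymer_min) |
    mate_has_homopolymer(reads$seq2, thresholds$homopolymer_min)
  q_bad <- mate_mean_phred(reads$qual1) < thresholds$mean_phred_min |
    mate_mean_phred(reads$qual2) < thresholds$mean_phred_min
  reason <- rep(NA_character_, nrow(reads))
  reason[q_bad] <- "low_quality"
  reason[hp_bad] <- "homopolymer"
  reason[n_bad] <- "unknown_nt"   # first rule wins, so assigned last
  out <- data.frame(id = reads$id,
                    verdict = ifelse(is.na(reason), "keep", "drop"),
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "reads") <- reads
  out
}

#' Filter verdict for a single read pair
#'
#' @param pair A one-row read data.frame, or a list with `id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`.
#' @param thresholds A [filter_thresholds()].
#' @return A list `verdict` (`"keep"`/`"drop"`) and `reason`.
#' @export
filter_read_pair <- function(pair, thresholds = filter_thresholds()) {
  df <- as.data.frame(pair, stringsAsFactors = FALSE)
  v <- filter_read_pairs(df, thresholds)
  list(verdict = v$verdict[1], reason = v$reason[1])
}

#' Trim the 5' end of both mates
#'
#' Removes the first `k` bases and the first `k` quality scores from each
#' mate; ids are preserved. Composition holds:
#' `trim(a)` then `trim(b)` equals `trim(a + b)`.
#'
#' @param reads Read-pair data.frame.
#' @param k Bases to remove; must be smaller than every mate length.
#' @return The trimmed data.frame.
#' @export
trim_five_prime <- function(reads, k) {
  k <- as.integer(k)
  if (k == 0) return(reads)
  if (k < 0) stopf("k must be >= 0")
  if (any(nchar(reads$seq1) <= k) || any(nchar(reads$seq2) <= k))
    stopf("trim length %d not smaller than every mate length", k)
  reads$seq1 <- substring(reads$seq1, k + 1L)
  reads$seq2 <- substring(reads$seq2, k + 1L)
  reads$qual1 <- substring(reads$qual1, k + 1L)
  reads$qual2 <- substring(reads$qual2, k + 1L)
  reads
}

#' Per-position nucleotide composition of a read set
#'
#' Exact tallies of A/C/G/T/N over the first `P` positions, the standard
#' per-cycle composition diagnostic for 5' priming bias.
#'
#' @param seqs Character vector of read sequences (or a read-pair
#'   data.frame, in which case both mates are profiled).
#' @param P Number of leading positions to profile; must not exceed the
#'   shortest read.
#' @return An object of class `nucleotide_profile`: a 5 x P count matrix
#'   (rows A, C, G, T, N) with attribute `total` (number of reads).
#' @export
nucleotide_profile <- function(seqs, P) {
  if (is.data.frame(seqs)) seqs <- c(seqs$seq1, seqs$seq2)
  if (length(seqs) == 0) stopf("no reads to profile")
  if (P > min(nchar(seqs))) stopf("P exceeds the minimum read length")
  bases <- c("A", "C", "G", "T", "N")
  m <- vapply(seq_len(P), function(p) {
    tab <- table(factor(substr(seqs, p, p), levels = bases))
    as.numeric(tab)
  }, numeric(5))
  rownames(m) <- bases
  colnames(m) <- seq_len(P)
  structure(m, total = length(seqs), class = "nucleotide_profile")
}

#' @export
print.nucleotide_profile <- function(x, ...) {
  cat(sprintf("Nucleotide profile over %d positions (%d reads)\n",
              ncol(x), attr(x, "total")))
  fr <- round(sweep(unclass(x), 2, attr(x, "total"), "/"), 3)
  print(fr[, seq_len(min(ncol(fr), 12L))])
  invisible(x)
}

#' Write a nucleotide profile as TSV (counts and fractions)
#'
#' @param profile A [nucleotide_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  fr <- sweep(unclass(profile), 2, attr(profile, "total"), "/")
  df <- data.frame(position = as.integer(colnames(profile)),
                   t(unclass(profile)), t(fr))
  names(df) <- c("position", paste0("n_", rownames(profile)),
                 paste0("frac_", rownames(profile)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scalar 5' composition-bias score
#'
#' The maximum, over the first `m` positions, of the total-variation
#' distance between that position's base distribution and the pooled base
#' distribution of positions `m+1 .. P`. 0 means no detectable bias; 1 is
#' maximal. Invariant to the number of reads profiled.
#'
#' @param profile A [nucleotide_profile()] covering at least `m + 10`
#'   positions.
#' @param m Number of leading positions suspected of bias (default 10).
#' @return A scalar in `[0, 1]`.
#' @export
bias_score <- function(profile, m = 10) {
  x <- unclass(profile)
  P <- ncol(x)
  if (P < m + 10) stopf("profile must cover at least m + 10 positions")
  pooled <- rowSums(x[, (m + 1):P, drop = FALSE])
  if (sum(pooled) == 0) stopf("degenerate pooled distribution")
  pooled <- pooled / sum(pooled)
  tv <- vapply(seq_len(m), function(p) {
    f <- x[, p] / sum(x[, p])
    0.5 * sum(abs(f - pooled))
  }, numeric(1))
  max(tv)
}
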