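# FASTQ and minimal-SAM I/O. FASTQ goes through Biostrings; the SAM dialect
# used by the simulator (header @SQ lines; QNAME FLAG RNAME POS MAPQ CIGAR
# RNEXT PNEXT TLEN SEQ QUAL; single-M CIGARs; paired/proper/strand/mate
# flags only) is read and written directly since no installed package
# parses text SAM.

#' Write paired reads as two FASTQ files
#'
#' Phred+33, 4-line records, mate ids suffixed `/1` and `/2`.
#'
#' @param reads Data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param prefix Output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(s) <- paste0(reads$id, "/", m)
    q <- Biostrings::BStringSet(reads[[paste0("qual", m)]])
    Biostrings::writeXStringSet(s, paths[m], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 Mate FASTQ files (`/1`, `/2` id suffixes are dropped).
#' @return Data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    s <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    data.frame(id = sub("/[12]$", "", names(s)),
               seq = as.character(s),
               qual = as.character(S4Vectors::mcols(s)$qualities),
               stringsAsFactors = FALSE)
  }
  a <- rd(path1); b <- rd(path2)
  if (!identical(a$id, b$id)) {
    b <- b[match(a$id, b$id), ]
    if (anyNA(b$id)) stopf("mate files do not contain the same read ids")
  }
  data.frame(id = a$id, seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(qname = character(0), mate = integer(0), rname = character(0),
             pos = integer(0), strand = character(0), alen = integer(0),
             mapq = integer(0), squal = numeric(0), seq = character(0),
             qual = character(0), stringsAsFactors = FALSE)
}

#' Write alignment records as SAM
#'
#' Emits `@SQ` header lines and one record per mate with flags limited to
#' paired/proper/strand/mate-strand/first/second, a single-`M` CIGAR, and
#' 1-based positions (internal coordinates are 0-based).
#'
#' @param alignments Alignment data.frame (`qname`, `mate`, `rname`, `pos`,
#'   `strand`, `alen`, `mapq`, `seq`, `qual`).
#' @param annotation Annotation (for `@SQ` reference lengths); may be `NULL`,
#'   in which case lengths are taken as the max end seen per reference.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, annotation, path) {
  a <- alignments
  key <- paste(a$qname, a$mate)
  other <- match(paste(a$qname, 3L - a$mate), key)
  if (anyNA(other)) stopf("write_sam: unpaired records present")
  flag <- 1L + 2L +
    ifelse(a$strand == "-", 16L, 0L) +
    ifelse(a$strand[other] == "-", 32L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L)
  left <- pmin(a$pos, a$pos[other])
  right <- pmax(a$pos + a$alen, a$pos[other] + a$alen[other])
  tlen <- ifelse(a$pos <= a$pos[other], right - left, -(right - left))
  if (!is.null(annotation)) {
    lens <- nchar(annotation$sequences)
    refs <- names(annotation$sequences)
  } else {
    refs <- unique(a$rname)
    lens <- vapply(refs, function(r) max(a$pos[a$rname == r] + a$alen[a$rname == r]),
                   numeric(1))
  }
  hdr <- sprintf("@SQ\tSN:%s\tLN:%d", refs, as.integer(lens))
  seqf <- if (!is.null(a$seq)) a$seq else strrep("N", a$alen)
  qualf <- if (!is.null(a$qual)) a$qual else strrep("I", a$alen)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                 a$qname, flag, a$rname, a$pos + 1L, a$mapq, a$alen,
                 a$pos[other] + 1L, tlen, seqf, qualf)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' @param path SAM file in the dialect written by [write_sam()].
#' @return Alignment data.frame with 0-based `pos`, mate index decoded from
#'   the flag, per-record summed base quality `squal`, and the `@SQ`
#'   reference lengths as the `refs` attribute.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- stats::setNames(
    as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  if (length(body) == 0) {
    out <- empty_alignments(); attr(out, "refs") <- refs; return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  if (!all(grepl("^\\d+M$", cigar)))
    stopf("read_sam: only single-M CIGARs are supported")
  out <- data.frame(
    qname = get(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    rname = get(3),
    pos = as.integer(get(4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    alen = as.integer(sub("M$", "", cigar)),
    mapq = as.integer(get(5)),
    seq = get(10),
    qual = get(11),
    stringsAsFactors = FALSE)
  out$squal <- vapply(out$qual, function(q) sum(utf8ToInt(q) - 33L), numeric(1),
                      USE.NAMES = FALSE)
  attr(out, "refs") <- refs
  out
}

#' Assemble proper read pairs into fragments
#'
#' Joins mate records that share a read id on the same reference into
#' fragment-level records carrying the full fragment interval, the
#' orientation signature, the minimum mapping quality and the summed base
#' quality. Orphan mates (missing or cross-reference partner) are excluded
#' and tallied.
#'
#' @param alignments Alignment data.frame as returned by [read_sam()].
#' @return Data frame of fragments (`qname`, `rname`, `start`, `end`,
#'   `orientation`, `start1`, `end1`, `start2`, `end2`, `mapq_min`,
#'   `squal`), with the orphan count as attribute `orphans`.
#' @export
pair_fragments <- function(alignments) {
  a <- alignments
  m1 <- a[a$mate == 1L, ]
  m2 <- a[a$mate == 2L, ]
  i <- match(m1$qname, m2$qname)
  ok <- !is.na(i)
  m2 <- m2[i[ok], ]; m1 <- m1[ok, ]
  same_ref <- m1$rname == m2$rname
  orphans <- (nrow(a) - 2L * sum(ok)) + 2L * sum(!same_ref)
  m1 <- m1[same_ref, ]; m2 <- m2[same_ref, ]
  left1 <- m1$pos <= m2$pos
  frag <- data.frame(
    qname = m1$qname,
    rname = m1$rname,
    start = pmin(m1$pos, m2$pos),
    end = pmax(m1$pos + m1$alen, m2$pos + m2$alen),
    orientation = ifelse(left1, paste0(m1$strand, m2$strand),
                         paste0(m2$strand, m1$strand)),
    start1 = m1$pos, end1 = m1$pos + m1$alen,
    start2 = m2$pos, end2 = m2$pos + m2$alen,
    mapq_min = pmin(m1$mapq, m2$mapq),
    squal = m1$squal + m2$squal,
    stringsAsFactors = FALSE)
  attr(frag, "orphans") <- orphans
  frag
}
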