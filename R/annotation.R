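#' Build a synthetic annotation: reference sequences and gene models
#'
#' Lays out `n_genes` non-overlapping multi-exon genes across two reference
#' sequences, plus a driver transgene on its own separate reference (the
#' transgene is quantified against its own sequence, so absence of reads is
#' meaningful). Deterministic for a fixed `config$seed`.
#'
#' Coordinates are 0-based half-open internally; GTF output is 1-based
#' closed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `annotation`: a list with `exons` (data.frame
#'   `gene_id`, `ref`, `strand`, `start`, `end`), `genes` (data.frame
#'   `gene_id`, `ref`, `strand`, `union_length`), and `sequences` (named
#'   character vector of reference sequences).
#' @export
build_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    refs <- c("ref_1", "ref_2")
    cursor <- stats::setNames(rep(200L, length(refs)), refs)
    rows <- vector("list", n + 1L)
    for (i in seq_len(n)) {
      ref <- refs[(i - 1L) %% length(refs) + 1L]
      strand <- sample(c("+", "-"), 1)
      # gene_001 is the designated knockdown target: a compact
      # single-exon 2 kb gene, so fragment placement along it is exactly
      # uniform and the region audit has a clean baseline
      n_ex <- if (i == 1L) 1L else sample(1:5, 1)
      ex_len <- if (i == 1L) 2000L else sample(400:800, n_ex, replace = TRUE)
      introns <- if (n_ex > 1) sample(60:300, n_ex - 1, replace = TRUE) else integer(0)
      starts <- cursor[ref] + c(0L, cumsum(ex_len[-n_ex] + introns))
      rows[[i]] <- data.frame(
        gene_id = sprintf("gene_%03d", i), ref = ref, strand = strand,
        start = as.integer(starts), end = as.integer(starts + ex_len),
        stringsAsFactors = FALSE)
      cursor[ref] <- max(rows[[i]]$end) + sample(300:800, 1)
    }
    rows[[n + 1L]] <- data.frame(
      gene_id = "transgene", ref = "ref_transgene", strand = "+",
      start = 200L, end = 1400L, stringsAsFactors = FALSE)
    exons <- do.call(rbind, rows)
    seq_len_by_ref <- tapply(exons$end, exons$ref, max) + 200L
    sequences <- vapply(seq_len_by_ref, random_dna, character(1))
    genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      data.frame(gene_id = e$gene_id[1], ref = e$ref[1], strand = e$strand[1],
                 union_length = sum(e$end - e$start), stringsAsFactors = FALSE)
    }))
    genes <- genes[order(match(genes$gene_id, unique(exons$gene_id))), ]
    rownames(genes) <- genes$gene_id
    structure(list(exons = exons, genes = genes, sequences = sequences),
              class = "annotation")
  })
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("Synthetic annotation: %d genes on %d references (%d exons)\n",
              nrow(x$genes), length(x$sequences), nrow(x$exons)))
  invisible(x)
}

#' Write gene models to GTF
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes, converting internal 0-based half-open coordinates to GTF
#' 1-based closed.
#'
#' @param annotation An `annotation` object (or any list with an `exons`
#'   data.frame in the same layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  e <- annotation$exons
  e <- e[order(e$ref, e$start), ]
  lines <- sprintf(
    '%s\ttissueqc_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    e$ref, e$start + 1L, e$end, e$strand, e$gene_id, e$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `exon` features (via rtracklayer) and converts them to the
#' package's internal 0-based half-open exon table, with per-gene union-exon
#' lengths (overlapping exons merged).
#'
#' @param path GTF file.
#' @return An `annotation` object without reference sequences.
#' @export
read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gtf() requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  exons <- data.frame(
    gene_id = as.character(gr$gene_id),
    ref = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    data.frame(gene_id = e$gene_id[1], ref = e$ref[1], strand = e$strand[1],
               union_length = sum(IRanges::width(ir)), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- genes$gene_id
  structure(list(exons = exons, genes = genes, sequences = NULL),
            class = "annotation")
}

# Exons of one gene in transcript (5'->3') order, with cumulative transcript
# offsets. Used to map transcript coordinates to genomic blocks.
gene_tx_map <- function(annotation, gene_id) {
  e <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  if (nrow(e) == 0) stopf("unknown gene '%s'", gene_id)
  e <- e[order(e$start), ]
  if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), ]
  len <- e$end - e$start
  list(exons = e, len = len, offset = cumsum(c(0L, len))[seq_along(len)],
       total = sum(len), strand = e$strand[1], ref = e$ref[1])
}

# Spliced transcript sequence (5'->3') of a gene.
gene_tx_seq <- function(annotation, gene_id) {
  m <- gene_tx_map(annotation, gene_id)
  ref_seq <- annotation$sequences[[m$ref]]
  pieces <- substring(ref_seq, m$exons$start + 1L, m$exons$end)
  if (m$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

# Map a transcript interval [a, b) (0-based) that lies within a single exon
# to a genomic interval. Returns c(start, end) 0-based half-open, plus the
# genomic strand of a forward (transcript-sense) read.
tx_to_genomic <- function(map, a, b) {
  idx <- findInterval(a, map$offset)
  ex <- map$exons[idx, ]
  off <- map$offset[idx]
  if (b > off + (ex$end - ex$start))
    stopf("transcript interval [%d,%d) crosses an exon boundary", a, b)
  if (map$strand == "+") c(ex$start + (a - off), ex$start + (b - off))
  else c(ex$end - (b - off), ex$end - (a - off))
}

# Vectorized check: does transcript interval [a, b) sit inside one exon?
tx_single_exon <- function(map, a, b) {
  idx <- findInterval(a, map$offset)
  b <= map$offset[idx] + map$len[idx]
}

# Map a genomic interval on the gene's reference to transcript coordinates
# (of the overlapping exonic part). Returns c(start, end) or NULL if the
# interval misses all exons.
genomic_to_tx <- function(map, gstart, gend) {
  hits <- which(map$exons$start < gend & map$exons$end > gstart)
  if (length(hits) == 0) return(NULL)
  tx <- unlist(lapply(hits, function(i) {
    s <- max(gstart, map$exons$start[i]); e <- min(gend, map$exons$end[i])
    if (map$strand == "+")
      c(map$offset[i] + (s - map$exons$start[i]),
        map$offset[i] + (e - map$exons$start[i]))
    else
      c(map$offset[i] + (map$exons$end[i] - e),
        map$offset[i] + (map$exons$end[i] - s))
  }))
  c(min(tx), max(tx))
}
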