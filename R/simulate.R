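#' Draw negative-binomial counts for one library
#'
#' Counts for gene g are drawn with mean
#' `mu_g = library_size * a_g / sum(a)` and variance `mu_g + alpha * mu_g^2`
#' (`alpha = 0` gives Poisson draws).
#'
#' @param abundances Non-negative expected abundance vector (any scale).
#' @param library_size Expected total fragments.
#' @param alpha NB dispersion, `>= 0`.
#' @param seed Optional seed for a private RNG stream.
#' @return Integer vector of counts, named like `abundances`.
#' @export
simulate_counts <- function(abundances, library_size, alpha, seed = NULL) {
  if (any(abundances < 0)) stopf("abundances must be >= 0")
  if (alpha < 0) stopf("alpha must be >= 0")
  if (library_size <= 0) stopf("library_size must be > 0")
  mu <- library_size * abundances / sum(abundances)
  with_seed(seed, {
    k <- if (alpha == 0) rpois(length(mu), mu)
         else rnbinom(length(mu), mu = mu, size = 1 / alpha)
    stats::setNames(as.integer(k), names(abundances))
  })
}

#' Simulate the count matrix of a whole experiment
#'
#' One NB count column per library in `config$libraries`, each from its own
#' mixture expectation ([mixture_abundance()]): WT libraries use `r = 1`,
#' KD libraries the configured knockdown ratio, and each library its own
#' contaminant fraction and transgene scale.
#'
#' @param config A [simulation_config()].
#' @param profiles Optional precomputed [build_profiles()]; built (with its
#'   annotation) when omitted.
#' @param annotation Optional precomputed [build_annotation()].
#' @return An object of class `count_matrix`: list with `counts` (genes x
#'   libraries integer matrix), `libraries` (the config sheet), `profiles`,
#'   `annotation`.
#' @export
simulate_counts_matrix <- function(config, profiles = NULL, annotation = NULL) {
  if (is.null(annotation)) annotation <- build_annotation(config)
  if (is.null(profiles)) profiles <- build_profiles(config, annotation)
  libs <- config$libraries
  with_seed(config$seed + 2L, {
    cols <- lapply(seq_len(nrow(libs)), function(j) {
      r <- if (libs$group[j] == "KD") config$knockdown_ratio else 1
      a <- mixture_abundance(profiles, config$phi, libs$contamination[j], r,
                             somatic = config$somatic_knockdown,
                             transgene_scale = libs$transgene_scale[j])
      simulate_counts(a, config$library_size, config$dispersion)
    })
    counts <- do.call(cbind, cols)
    colnames(counts) <- libs$label
    structure(list(counts = counts, libraries = libs, profiles = profiles,
                   annotation = annotation), class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d libraries (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(table(x$libraries$group)),
                    table(x$libraries$group), sep = "=", collapse = ", ")))
  invisible(x)
}

# Draw one fragment per count on the spliced transcript: uniform placement
# subject to both mates sitting inside a single exon each (so every truth
# alignment is one contiguous genomic block). Falls back to a placement
# inside the longest exon when rejection sampling fails.
place_fragments <- function(map, n, read_length, frag_range) {
  if (n == 0L)
    return(data.frame(start = integer(0), len = integer(0)))
  L <- map$total
  len <- sample(seq(frag_range[1], frag_range[2]), n, replace = TRUE)
  len <- pmin(len, L)
  start <- floor(runif(n, 0, L - len + 1))
  for (tries in 1:25) {
    bad <- !(tx_single_exon(map, start, start + read_length) &
             tx_single_exon(map, start + len - read_length, start + len))
    if (!any(bad)) break
    len[bad] <- pmin(sample(seq(frag_range[1], frag_range[2]), sum(bad),
                            replace = TRUE), L)
    start[bad] <- floor(runif(sum(bad), 0, L - len[bad] + 1))
  }
  bad <- !(tx_single_exon(map, start, start + read_length) &
           tx_single_exon(map, start + len - read_length, start + len))
  if (any(bad)) {  # guaranteed placement inside the longest exon
    ex <- which.max(map$len)
    len[bad] <- pmin(len[bad], map$len[ex])
    start[bad] <- map$offset[ex] +
      floor(runif(sum(bad), 0, map$len[ex] - len[bad] + 1))
  }
  data.frame(start = as.integer(start), len = as.integer(len))
}

# Re-draw the first `p` cycles of each read from the bias-profile-skewed
# composition. profile: 4 x p multiplier matrix (A,C,G,T rows).
apply_bias <- function(seqs, profile) {
  if (length(seqs) == 0) return(seqs)
  p <- ncol(profile)
  bases <- rownames(profile)
  cols <- lapply(seq_len(p), function(j) {
    w <- profile[, j] / sum(profile[, j])
    sample(bases, length(seqs), replace = TRUE, prob = w)
  })
  heads <- do.call(paste0, cols)
  paste0(heads, substring(seqs, p + 1L))
}

# Quality string helpers (Phred+33).
phred_string <- function(q, len) {
  vapply(seq_along(q), function(i)
    strrep(intToUtf8(q[i] + 33L), len), character(1))
}

#' Simulate reads and truth alignments for one library
#'
#' Turns one count column into paired reads plus ground-truth alignment
#' records. Fragments are placed uniformly on each gene's spliced
#' transcript, with lengths uniform over `config$fragment_length`; mate
#' orientation is random (unstranded protocol). On top of the clean
#' fragments the generator injects, each labeled in the truth table:
#'
#' * exact positional PCR duplicates at rate
#'   `d_max * exp(-lambda * cdna_input)`,
#' * QC-failing classes (a read with an 'N'; a >= 50 nt homopolymer run;
#'   mean Phred < 30; low-quality first 10 cycles rescued by trimming),
#' * optionally, double-stranded shRNA transgene read pairs drawn in both
#'   orientations from the 3' targeted half of the knockdown target (KD
#'   libraries only).
#'
#' The first `config$bias_positions` cycles of every mate are re-drawn from
#' the bias-profile-skewed base composition.
#'
#' @param counts Named count column (from [simulate_counts()]).
#' @param annotation [build_annotation()] output (with sequences).
#' @param config The [simulation_config()].
#' @param library Row of `config$libraries` for this library (data.frame of
#'   one row); defaults to the first row.
#' @param target_gene Gene id of the knockdown target (needed when
#'   `shrna_rate > 0`); shRNA pairs are drawn from its 3' half.
#' @param seed Optional private seed.
#' @return List with `reads` (data.frame `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), `alignments` (alignment record data.frame, see
#'   [read_sam()]), and `truth` (data.frame `id`, `gene_id`, `category`).
#' @export
simulate_reads <- function(counts, annotation, config,
                           library = config$libraries[1, ],
                           target_gene = NULL, seed = NULL) {
  stopifnot(inherits(annotation, "annotation"))
  rl <- config$read_length
  with_seed(seed, {
    frags <- list(); k <- 0L
    for (g in names(counts)) {
      n <- counts[[g]]
      if (n == 0L) next
      map <- gene_tx_map(annotation, g)
      if (map$total < config$fragment_length[1]) {
        warnf("gene %s transcript (%d bp) shorter than minimum fragment; skipped",
              g, map$total)
        next
      }
      pl <- place_fragments(map, n, rl, config$fragment_length)
      k <- k + 1L
      frags[[k]] <- data.frame(gene_id = g, start = pl$start, len = pl$len,
                               stringsAsFactors = FALSE)
    }
    frags <- if (k) do.call(rbind, frags) else
      data.frame(gene_id = character(0), start = integer(0), len = integer(0))
    n_orig <- nrow(frags)
    frags$id <- sprintf("frag_%06d", seq_len(max(n_orig, 0L)))
    frags$category <- rep("keep", n_orig)
    frags$swap <- sample(c(TRUE, FALSE), n_orig, replace = TRUE)
    frags$source <- frags$id

    # --- PCR duplicates: whole-pair copies at input-dependent rate -------
    d <- config$duplicate_d_max * exp(-config$duplicate_lambda * library$cdna_input)
    n_dup <- round(d / (1 - d) * n_orig)
    if (n_dup > 0 && n_orig > 0) {
      src <- frags[sample(n_orig, n_dup, replace = TRUE), ]
      src$id <- sprintf("dup_%06d", seq_len(n_dup))
      src$category <- "duplicate"
      frags <- rbind(frags, src)
    }

    # --- corrupted read classes: extra pairs with fresh placements ------
    add_class <- function(frags, cls, rate) {
      n <- round(rate * n_orig)
      if (n == 0 || n_orig == 0) return(frags)
      gene <- sample(frags$gene_id[seq_len(n_orig)], n, replace = TRUE)
      pieces <- lapply(unique(gene), function(g) {
        m <- sum(gene == g)
        pl <- place_fragments(gene_tx_map(annotation, g), m,
                              rl, config$fragment_length)
        data.frame(gene_id = g, start = pl$start, len = pl$len,
                   stringsAsFactors = FALSE)
      })
      src <- do.call(rbind, pieces)
      src$id <- sprintf("%s_%06d", cls, seq_len(n))
      src$category <- cls
      src$swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
      src$source <- src$id
      rbind(frags, src)
    }
    for (cls in names(config$corrupt_rates))
      frags <- add_class(frags, cls, config$corrupt_rates[[cls]])

    # --- shRNA transgene pairs from the 3' targeted half (KD only) -------
    if (config$shrna_rate > 0 && identical(library$group, "KD")) {
      if (is.null(target_gene)) stopf("target_gene required when shrna_rate > 0")
      tmap <- gene_tx_map(annotation, target_gene)
      half <- floor(tmap$total / 2)
      n_sh <- round(config$shrna_rate * n_orig)
      if (n_sh > 0) {
        len <- pmin(sample(seq(config$fragment_length[1],
                               config$fragment_length[2]),
                           n_sh, replace = TRUE), tmap$total - half)
        st <- half + floor(runif(n_sh, 0, (tmap$total - half) - len + 1))
        sh <- data.frame(gene_id = target_gene, start = as.integer(st),
                         len = as.integer(len),
                         id = sprintf("shrna_%06d", seq_len(n_sh)),
                         category = "shrna",
                         swap = sample(c(TRUE, FALSE), n_sh, replace = TRUE),
                         source = sprintf("shrna_%06d", seq_len(n_sh)),
                         stringsAsFactors = FALSE)
        # force valid single-exon mates via the standard fallback
        bad <- !(tx_single_exon(tmap, sh$start, sh$start + rl) &
                 tx_single_exon(tmap, sh$start + sh$len - rl, sh$start + sh$len))
        if (any(bad)) {
          ex <- which(tmap$offset >= half - 1e-9)
          ex <- if (length(ex)) ex[which.max(tmap$len[ex])] else length(tmap$len)
          sh$len[bad] <- pmin(sh$len[bad], tmap$len[ex])
          sh$start[bad] <- tmap$offset[ex] +
            floor(runif(sum(bad), 0, tmap$len[ex] - sh$len[bad] + 1))
        }
        frags <- rbind(frags, sh)
      }
    }

    build_library_reads(frags, annotation, config)
  })
}

# Materialize sequences, qualities, bias, corruption patterns and alignment
# records for a fragment table. Duplicates copy their source pair byte for
# byte (same molecule, same priming).
build_library_reads <- function(frags, annotation, config) {
  rl <- config$read_length
  n <- nrow(frags)
  if (n == 0) {
    return(list(reads = data.frame(id = character(0), seq1 = character(0),
                                   qual1 = character(0), seq2 = character(0),
                                   qual2 = character(0)),
                alignments = empty_alignments(),
                truth = data.frame(id = character(0), gene_id = character(0),
                                   category = character(0))))
  }
  txseq <- new.env(parent = emptyenv())
  maps <- new.env(parent = emptyenv())
  for (g in unique(frags$gene_id)) {
    assign(g, gene_tx_seq(annotation, g), envir = txseq)
    assign(g, gene_tx_map(annotation, g), envir = maps)
  }
  seqs <- vapply(frags$gene_id, function(g) get(g, envir = txseq), character(1))
  fwd <- substring(seqs, frags$start + 1L, frags$start + rl)
  rev_ <- revcomp(substring(seqs, frags$start + frags$len - rl + 1L,
                            frags$start + frags$len))
  seq1 <- ifelse(frags$swap, rev_, fwd)
  seq2 <- ifelse(frags$swap, fwd, rev_)

  # 5' composition bias on freshly sequenced molecules
  is_dup <- frags$category == "duplicate"
  seq1[!is_dup] <- apply_bias(seq1[!is_dup], config$bias_profile[, seq_len(config$bias_positions), drop = FALSE])
  seq2[!is_dup] <- apply_bias(seq2[!is_dup], config$bias_profile[, seq_len(config$bias_positions), drop = FALSE])

  baseq <- sample(35:39, n, replace = TRUE)
  qual1 <- phred_string(baseq, rl)
  qual2 <- phred_string(sample(35:39, n, replace = TRUE), rl)

  # deterministic corruption patterns
  cls <- frags$category
  i <- which(cls == "n_read")
  if (length(i)) substr(seq1[i], 45, 45) <- "N"
  i <- which(cls == "homopolymer")
  if (length(i)) seq1[i] <- paste0(strrep("A", 60), substring(seq1[i], 61))
  i <- which(cls == "low_quality")
  if (length(i)) qual2[i] <- strrep(intToUtf8(25L + 33L), rl)
  i <- which(cls == "qual5p")
  if (length(i)) {
    q5 <- paste0(strrep(intToUtf8(2L + 33L), 10L),
                 strrep(intToUtf8(32L + 33L), rl - 10L))
    qual1[i] <- q5; qual2[i] <- q5
  }

  # duplicates copy their source pair exactly
  if (any(is_dup)) {
    src <- match(frags$source[is_dup], frags$id)
    seq1[is_dup] <- seq1[src]; seq2[is_dup] <- seq2[src]
    qual1[is_dup] <- qual1[src]; qual2[is_dup] <- qual2[src]
  }

  # truth alignments (one contiguous block per mate, by construction)
  aln <- lapply(seq_len(n), function(i) {
    map <- get(frags$gene_id[i], envir = maps)
    a <- frags$start[i]; b <- a + frags$len[i]
    g1 <- tx_to_genomic(map, a, a + rl)          # transcript-5' mate
    g2 <- tx_to_genomic(map, b - rl, b)          # transcript-3' mate
    s1 <- if (map$strand == "+") "+" else "-"
    s2 <- if (map$strand == "+") "-" else "+"
    if (frags$swap[i]) { tmp <- g1; g1 <- g2; g2 <- tmp
                         tmp <- s1; s1 <- s2; s2 <- tmp }
    data.frame(qname = frags$id[i], mate = 1:2, rname = map$ref,
               pos = c(g1[1], g2[1]), strand = c(s1, s2), alen = rl,
               mapq = 50L, stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, aln)
  sq <- vapply(seq_len(n), function(i)
    c(sum(utf8ToInt(qual1[i]) - 33L), sum(utf8ToInt(qual2[i]) - 33L)),
    numeric(2))
  aln$squal <- as.vector(sq)
  aln$seq <- as.vector(t(cbind(seq1, seq2)))
  aln$qual <- as.vector(t(cbind(qual1, qual2)))

  list(reads = data.frame(id = frags$id, seq1 = seq1, qual1 = qual1,
                          seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE),
       alignments = aln,
       truth = data.frame(id = frags$id, gene_id = frags$gene_id,
                          category = frags$category, stringsAsFactors = FALSE))
}

#' Simulate a full experiment to disk
#'
#' Writes, per library, paired FASTQ files, a truth SAM file and a truth
#' table (TSV with the generating gene and artifact category of every
#' pair), plus the GTF annotation, the library sheet and the marker panel.
#' Byte-reproducible for a fixed configuration.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `annotation`, `profiles`, per-library
#'   truth tables and the vector of written files.
#' @export
simulate_experiment <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  annotation <- build_annotation(config)
  profiles <- build_profiles(config, annotation)
  write_gtf(annotation, file.path(dir, "annotation.gtf"))
  write.table(config$libraries, file.path(dir, "libraries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- marker_panel(profiles, annotation)
  write_panel(panel, file.path(dir, "panel.json"))
  cm <- simulate_counts_matrix(config, profiles, annotation)
  write.table(data.frame(gene_id = rownames(cm$counts), cm$counts,
                         check.names = FALSE),
              file.path(dir, "true_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  libs <- config$libraries
  truth <- list()
  for (j in seq_len(nrow(libs))) {
    sim <- simulate_reads(cm$counts[, j], annotation, config,
                          library = libs[j, ],
                          target_gene = profiles$markers$knockdown_target,
                          seed = config$seed + 100L + j)
    pre <- file.path(dir, libs$label[j])
    write_fastq_pairs(sim$reads, pre)
    write_sam(sim$alignments, annotation, paste0(pre, ".sam"))
    write.table(sim$truth, paste0(pre, ".truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth[[libs$label[j]]] <- sim$truth
  }
  invisible(list(annotation = annotation, profiles = profiles,
                 counts = cm, truth = truth, dir = dir))
}
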