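# Shared simulation fixtures, built once per test run and cached.

.tq_cache <- new.env(parent = emptyenv())

tq_cached <- function(key, expr) {
  if (!exists(key, envir = .tq_cache)) assign(key, force(expr), envir = .tq_cache)
  get(key, envir = .tq_cache)
}

# Small standard experiment used by several files.
tq_config <- function(...) {
  simulation_config(n_genes = 25, library_size = 3000, seed = 101, ...)
}

tq_annotation <- function() tq_cached("ann", build_annotation(tq_config()))
tq_profiles <- function() tq_cached("prof",
  build_profiles(tq_config(), tq_annotation()))
tq_counts <- function() tq_cached("cm",
  simulate_counts_matrix(tq_config(), tq_profiles(), tq_annotation()))

# One simulated library (reads + truth) from the standard experiment.
tq_library_sim <- function() tq_cached("libsim", {
  cfg <- tq_config()
  simulate_reads(tq_counts()$counts[, 1], tq_annotation(), cfg,
                 library = cfg$libraries[1, ],
                 target_gene = tq_profiles()$markers$knockdown_target,
                 seed = 555)
})

# Hand-built read pair for boundary tests.
mk_pair <- function(id = "r1",
                    seq1 = strrep("ACGT", 25), qual1 = strrep("H", 100),
                    seq2 = strrep("TGCA", 25), qual2 = strrep("H", 100)) {
  data.frame(id = id, seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
             stringsAsFactors = FALSE)
}

phred_chr <- function(q) intToUtf8(q + 33L)

# Minimal hand-built annotation from an exon table (possibly several
# exons per gene).
mk_annotation <- function(genes) {
  gl <- do.call(rbind, lapply(split(genes, genes$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1], ref = e$ref[1], strand = e$strand[1],
               union_length = sum(e$end - e$start), stringsAsFactors = FALSE)))
  gl <- gl[order(match(gl$gene_id, unique(genes$gene_id))), ]
  rownames(gl) <- gl$gene_id
  structure(list(exons = genes, genes = gl, sequences = NULL),
            class = "annotation")
}

# Fragment-table row builder.
mk_frag <- function(qname, rname, s1, e1, s2, e2, mapq = 50, squal = 100,
                    orientation = "+-") {
  data.frame(qname = qname, rname = rname,
             start = pmin(s1, s2), end = pmax(e1, e2),
             orientation = orientation,
             start1 = s1, end1 = e1, start2 = s2, end2 = e2,
             mapq_min = mapq, squal = squal, stringsAsFactors = FALSE)
}
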