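test_that("duplicate removal keeps one best pair per fragment signature", {
  f <- rbind(mk_frag("a", "r", 100, 200, 300, 400, squal = 50),
             mk_frag("b", "r", 100, 200, 300, 400, squal = 80),
             mk_frag("c", "r", 100, 200, 300, 450, squal = 10))
  dd <- remove_duplicates(f)
  # two byte-identical signatures -> 1 kept (the higher summed quality)
  expect_equal(dd$n_removed, 1L)
  expect_true("b" %in% dd$kept_ids)
  expect_false("a" %in% dd$kept_ids)
  # same start but different fragment end -> both retained
  expect_true("c" %in% dd$kept_ids)
  expect_equal(dd$duplicate_rate, 1 / 3)
  # quality ties break by first occurrence
  ft <- rbind(mk_frag("x", "r", 1, 100, 200, 300, squal = 7),
              mk_frag("y", "r", 1, 100, 200, 300, squal = 7))
  expect_identical(remove_duplicates(ft)$kept_ids, "x")
  # orientation is part of the signature
  fo <- rbind(mk_frag("u", "r", 1, 100, 200, 300, orientation = "+-"),
              mk_frag("v", "r", 1, 100, 200, 300, orientation = "-+"))
  expect_equal(remove_duplicates(fo)$n_removed, 0L)
  # idempotence
  dd2 <- remove_duplicates(dd$fragments)
  expect_identical(dd2$fragments$qname, dd$fragments$qname)
  expect_equal(dd2$n_removed, 0L)
})

test_that("orphan mates are excluded and tallied", {
  sim <- tq_library_sim()
  aln <- head(sim$alignments, 21)  # last pair loses its mate
  frag <- pair_fragments(aln)
  expect_equal(attr(frag, "orphans"), 1L)
  expect_equal(nrow(frag), 10L)
})

test_that("duplicate rate recovers the injected fraction on simulated pairs", {
  sim <- tq_library_sim()
  keep <- sim$truth$id[sim$truth$category %in% c("keep", "duplicate")]
  frag <- pair_fragments(sim$alignments)
  dd <- remove_duplicates(frag[frag$qname %in% keep, ])
  injected <- mean(sim$truth$category[sim$truth$id %in% keep] == "duplicate")
  expect_lt(abs(dd$duplicate_rate - injected), 0.02)
})

test_that("duplicate/input diagnostic flags strong negative correlation", {
  # rates exactly linear in input -> |r| = 1
  inp <- c(2, 3, 4, 5, 6)
  d <- duplicate_input_diagnostic(0.9 - 0.1 * inp, inp, n_total = rep(1e4, 5))
  expect_equal(abs(d$r_rate), 1)
  expect_true(d$flag)
  # the generator's monotone construction gives r < -0.8
  rates <- 0.986 * exp(-0.15 * inp) * (1 + rnorm(5, 0, 0.01))
  expect_lt(duplicate_input_diagnostic(rates, inp)$r_rate, -0.8)
  # shuffled inputs kill the association on average
  set.seed(1)
  rs <- replicate(200, duplicate_input_diagnostic(rates, sample(inp))$r_rate)
  expect_lt(abs(mean(rs)), 0.15)
  # constant input -> undefined correlation, reported as NA
  expect_true(is.na(duplicate_input_diagnostic(rates, rep(4, 5))$r_rate))
  expect_error(duplicate_input_diagnostic(0.5, 2), "3 libraries")
})

test_that("union counting implements the union-mode rules", {
  ex <- data.frame(gene_id = c("A", "A", "B"), ref = "r", strand = "+",
                   start = c(0L, 500L, 900L), end = c(300L, 1000L, 1500L),
                   stringsAsFactors = FALSE)
  ann <- mk_annotation(ex)
  frags <- rbind(
    mk_frag("inA", "r", 10, 110, 150, 250),          # fully inside A
    mk_frag("ambig", "r", 100, 200, 920, 990),       # mate2 overlaps A and B
    mk_frag("outside", "r", 1600, 1700, 1800, 1900), # no feature
    mk_frag("lowq", "r", 10, 110, 150, 250, mapq = 3))
  cu <- count_union(frags, ann, min_mapq = 10)
  expect_equal(unname(cu$counts[["A"]]), 1L)
  expect_equal(unname(cu$counts[["B"]]), 0L)
  expect_equal(unname(cu$tallies),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(cu$tallies), nrow(frags))
  expect_error(count_union(mk_frag("z", "chrUnknown", 1, 50, 60, 100), ann),
               "unknown reference")
})

test_that("union counting agrees with a brute-force overlap oracle", {
  set.seed(20)
  n_genes <- 30
  starts <- cumsum(sample(500:1500, n_genes))
  ex <- data.frame(gene_id = sprintf("g%02d", 1:n_genes), ref = "r",
                   strand = "+", start = starts,
                   end = starts + sample(300:900, n_genes),
                   stringsAsFactors = FALSE)
  ann <- mk_annotation(ex)
  pos <- sample(max(ex$end), 500, replace = TRUE)
  frags <- mk_frag(sprintf("f%03d", 1:500), "r",
                   pos, pos + 100, pos + sample(50:300, 500, TRUE),
                   pos + sample(350:500, 500, TRUE))
  cu <- count_union(frags, ann, min_mapq = 10)
  oracle <- setNames(integer(n_genes), ex$gene_id)
  tal <- c(counted = 0L, ambiguous = 0L, no_feature = 0L)
  for (i in seq_len(nrow(frags))) {
    hit <- character(0)
    for (j in seq_len(n_genes)) {
      ov <- (frags$start1[i] < ex$end[j] & frags$end1[i] > ex$start[j]) ||
        (frags$start2[i] < ex$end[j] & frags$end2[i] > ex$start[j])
      if (ov) hit <- c(hit, ex$gene_id[j])
    }
    if (length(hit) == 1) { oracle[hit] <- oracle[hit] + 1L
                            tal["counted"] <- tal["counted"] + 1L }
    else if (length(hit) >= 2) tal["ambiguous"] <- tal["ambiguous"] + 1L
    else tal["no_feature"] <- tal["no_feature"] + 1L
  }
  expect_equal(unname(cu$counts), unname(oracle))
  expect_equal(unname(cu$tallies[c("counted", "ambiguous", "no_feature")]),
               unname(tal))
})

test_that("counting truth alignments recovers simulated counts exactly", {
  sim <- tq_library_sim()
  clean <- sim$truth$id[sim$truth$category == "keep"]
  frag <- pair_fragments(sim$alignments)
  cu <- count_union(frag[frag$qname %in% clean, ], tq_annotation(),
                    min_mapq = 0)
  truth <- tq_counts()$counts[, 1]
  expect_equal(unname(cu$counts[names(truth)]), unname(truth))
  expect_equal(unname(cu$tallies[["counted"]]), sum(truth))
})

test_that("FPKM normalizes by union-exon kb and counted millions", {
  # 10 fragments, 1,000 bp gene, 1,000,000 counted -> FPKM = 10
  expect_equal(unname(fpkm(c(g = 10), c(g = 1000), 1e6)), 10)
  # doubling counts and total leaves FPKM unchanged
  cts <- c(a = 10, b = 200); len <- c(a = 1000, b = 2500)
  expect_equal(fpkm(2 * cts, len, 2 * sum(cts)), fpkm(cts, len, sum(cts)))
  # counts are recoverable by inverting the formula
  f <- fpkm(cts, len, sum(cts))
  expect_equal(f * (len / 1e3) * (sum(cts) / 1e6), cts)
  expect_error(fpkm(c(g = 1), c(g = 0), 100), "zero-length")
  expect_error(fpkm(c(g = 1), c(g = 100), 0), "counted_total")
})

test_that("SAM round trip preserves alignment records", {
  sim <- tq_library_sim()
  aln <- head(sim$alignments, 200)
  p <- tempfile(fileext = ".sam")
  write_sam(aln, tq_annotation(), p)
  back <- read_sam(p)
  for (col in c("qname", "mate", "rname", "pos", "strand", "alen", "mapq",
                "seq", "qual"))
    expect_identical(back[[col]], aln[[col]], label = paste("column", col))
  expect_identical(attr(back, "refs"),
                   setNames(nchar(tq_annotation()$sequences),
                            names(tq_annotation()$sequences)))
})

test_that("FASTQ round trip preserves reads", {
  sim <- tq_library_sim()
  reads <- head(sim$reads, 100)
  pre <- tempfile()
  write_fastq_pairs(reads, pre)
  back <- read_fastq_pairs(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_identical(back, reads)
})
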