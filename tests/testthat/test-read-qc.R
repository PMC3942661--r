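test_that("filter drops pairs on the three rules with paper-order reasons", {
  th <- filter_thresholds()
  # 100-mer of all 'A' in one mate, partner clean -> homopolymer
  v <- filter_read_pair(mk_pair(seq1 = strrep("A", 100)), th)
  expect_identical(v, list(verdict = "drop", reason = "homopolymer"))
  # a single 'N' -> unknown_nt, and it outranks other failures
  pN <- mk_pair(seq1 = paste0("N", strrep("ACGT", 24), "ACG"))
  expect_identical(filter_read_pair(pN, th)$reason, "unknown_nt")
  pBoth <- mk_pair(seq1 = paste0("N", strrep("A", 99)),
                   qual2 = strrep(phred_chr(10), 100))
  expect_identical(filter_read_pair(pBoth, th)$reason, "unknown_nt")
  # mean Phred exactly at the threshold is kept (rule is strictly below)
  p30 <- mk_pair(qual1 = strrep(phred_chr(30), 100),
                 qual2 = strrep(phred_chr(30), 100))
  expect_identical(filter_read_pair(p30, th)$verdict, "keep")
  # either failing mate drops the pair
  pm2 <- mk_pair(qual2 = strrep(phred_chr(20), 100))
  expect_identical(filter_read_pair(pm2, th)$reason, "low_quality")
  # empty mate -> low_quality drop
  pe <- mk_pair(seq1 = "", qual1 = "")
  expect_identical(filter_read_pair(pe, th)$reason, "low_quality")
  # a run of 49 is below the default homopolymer threshold
  p49 <- mk_pair(seq1 = paste0(strrep("G", 49), strrep("ACGT", 12), "ACG"))
  expect_identical(filter_read_pair(p49, th)$verdict, "keep")
  # N does not extend a run
  pNrun <- mk_pair(seq1 = paste0(strrep("A", 30), "N", strrep("A", 30),
                                 strrep("CGT", 13)),
                   qual1 = strrep("H", 100))
  expect_identical(filter_read_pair(pNrun, filter_thresholds(max_n = 1,
                                                             homopolymer_min = 50))$verdict,
                   "keep")
})

test_that("a verdict depends only on pair content, not stream position", {
  sim <- tq_library_sim()
  reads <- head(sim$reads, 500)
  v1 <- filter_read_pairs(reads)
  idx <- rev(seq_len(nrow(reads)))
  v2 <- filter_read_pairs(reads[idx, ])
  expect_identical(v1$verdict[idx], v2$verdict)
  expect_identical(v1$reason[idx], v2$reason)
})

test_that("5' trimming removes bases and scores, composes, and rescues", {
  p <- mk_pair(seq1 = paste0(strrep("C", 10), strrep("ACGT", 22), "AC"),
               qual1 = paste0(strrep(phred_chr(2), 10),
                              strrep(phred_chr(33), 90)))
  t10 <- trim_five_prime(p, 10)
  expect_identical(nchar(t10$seq1), 90L)
  expect_identical(substr(t10$seq1, 1, 1), substr(p$seq1, 11, 11))
  expect_identical(t10$qual1, strrep(phred_chr(33), 90))
  expect_identical(trim_five_prime(p, 0), p)
  # composition: trim(a) then trim(b) == trim(a + b)
  expect_identical(trim_five_prime(trim_five_prime(p, 3), 7),
                   trim_five_prime(p, 10))
  expect_error(trim_five_prime(p, 100), "trim length")
  # boundary read: mean 29.9 untrimmed (dropped), 33 after trim(10) (kept)
  pb <- mk_pair(qual1 = paste0(strrep(phred_chr(2), 10),
                               strrep(phred_chr(33), 90)),
                qual2 = paste0(strrep(phred_chr(2), 10),
                               strrep(phred_chr(33), 90)))
  expect_identical(filter_read_pair(pb, filter_thresholds())$reason,
                   "low_quality")
  expect_identical(filter_read_pair(pb, filter_thresholds(trim5 = 10))$verdict,
                   "keep")
})

test_that("nucleotide profile tallies exactly and conserves counts", {
  prof <- nucleotide_profile(rep("ACGT", 4), 4)
  expect_equal(unname(prof["A", 1]), 4)
  expect_equal(unname(prof["C", 2]), 4)
  expect_true(all(colSums(prof) == 4))
  sim <- tq_library_sim()
  p <- nucleotide_profile(sim$reads, 20)
  expect_true(all(colSums(p) == attr(p, "total")))
  expect_error(nucleotide_profile(character(0), 4), "no reads")
  expect_error(nucleotide_profile(c("ACGT"), 10), "minimum read length")
})

test_that("bias score is the max TV distance against the pooled tail", {
  # position 1 always 'A', pooled distribution uniform -> TV = 0.75
  m <- matrix(25, nrow = 5, ncol = 20,
              dimnames = list(c("A", "C", "G", "T", "N"), 1:20))
  m["N", ] <- 0
  m[, 1] <- c(100, 0, 0, 0, 0)
  prof <- structure(m, total = 100, class = "nucleotide_profile")
  expect_equal(bias_score(prof, m = 10), 0.75)
  # invariant to read-count scaling
  prof2 <- structure(m * 13, total = 1300, class = "nucleotide_profile")
  expect_equal(bias_score(prof2, m = 10), 0.75)
  # needs enough tail positions and a non-degenerate pooled distribution
  expect_error(bias_score(prof, m = 15), "at least")
  m0 <- m; m0[, 11:20] <- 0
  expect_error(bias_score(structure(m0, total = 100,
                                    class = "nucleotide_profile"), 10),
               "degenerate")
})

test_that("simulator corruption classes are filtered with perfect accuracy", {
  sim <- tq_library_sim()
  bad_classes <- c("n_read", "homopolymer", "low_quality", "qual5p")
  v <- filter_read_pairs(sim$reads)
  truth_bad <- sim$truth$category %in% bad_classes
  pred_bad <- v$verdict == "drop"
  expect_equal(sum(pred_bad & truth_bad) / sum(pred_bad), 1)
  expect_equal(sum(pred_bad & truth_bad) / sum(truth_bad), 1)
  # trimming rescues exactly the 5'-quality class
  vt <- filter_read_pairs(sim$reads, filter_thresholds(trim5 = 10))
  rescued <- v$verdict == "drop" & vt$verdict == "keep"
  expect_setequal(unique(sim$truth$category[rescued]), "qual5p")
  expect_equal(sum(rescued), sum(sim$truth$category == "qual5p"))
})
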