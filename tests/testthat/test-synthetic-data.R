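test_that("annotation generation is deterministic and non-overlapping", {
  cfg <- tq_config()
  p1 <- tempfile(fileext = ".gtf"); p2 <- tempfile(fileext = ".gtf")
  write_gtf(build_annotation(cfg), p1)
  write_gtf(build_annotation(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))

  ann <- tq_annotation()
  # no two genes overlap on the same reference
  for (r in unique(ann$genes$ref)) {
    e <- ann$exons[ann$exons$ref == r, ]
    spans <- do.call(rbind, lapply(split(e, e$gene_id), function(d)
      c(min(d$start), max(d$end))))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  }
  # transgene on its own reference
  expect_identical(ann$genes["transgene", "ref"], "ref_transgene")
  expect_false("ref_transgene" %in% ann$genes$ref[ann$genes$gene_id != "transgene"])
})

test_that("emitted GTF carries one record set per gene plus the transgene", {
  cfg <- simulation_config(n_genes = 100, seed = 5)
  ann <- build_annotation(cfg)
  p <- tempfile(fileext = ".gtf")
  write_gtf(ann, p)
  ids <- sub('.*gene_id "([^"]+)".*', "\\1", readLines(p))
  expect_length(unique(ids), 101L)
  expect_true("transgene" %in% ids)
  # round trip through the GTF reader preserves models
  skip_if_not_installed("rtracklayer")
  back <- read_gtf(p)
  expect_setequal(back$genes$gene_id, ann$genes$gene_id)
  expect_equal(back$genes[ann$genes$gene_id, "union_length"],
               ann$genes$union_length)
})

test_that("annotation rejects degenerate sizes", {
  expect_error(simulation_config(n_genes = 5), "n_genes")
  expect_error(simulation_config(library_size = 0), "library_size")
  expect_error(simulation_config(read_length = 10), "read_length")
})

test_that("mixture abundance follows the signal-dilution formula", {
  prof <- structure(list(
    genes = data.frame(gene_id = c("target", "marker", "other"),
                       class = c("ubiquitous", "contaminant_specific", "ubiquitous"),
                       neuron = c(1, 0, 2), glia = c(1, 0, 2),
                       contaminant = c(1, 10, 2), response_beta = 0,
                       stringsAsFactors = FALSE),
    markers = list(knockdown_target = "target")), class = "tissue_profiles")
  # ubiquitous target, phi = 0.5, r = 0.2, c = 0 -> 0.6 of its WT value
  a <- mixture_abundance(prof, 0.5, 0, 0.2)
  expect_equal(unname(a[["target"]]), 0.5 * 0.2 + 0.5 * 1)
  # contaminant marker, c = 0.3, abundance 10 in contaminant tissue
  a2 <- mixture_abundance(prof, 0.5, 0.3, 1)
  expect_equal(unname(a2[["marker"]]), 3.0)
  # r = 1 reproduces the WT profile for any phi, c
  for (pc in list(c(0.3, 0), c(0.7, 0.4))) {
    aw <- mixture_abundance(prof, pc[1], pc[2], 1)
    ref <- (1 - pc[2]) * (pc[1] * prof$genes$neuron +
                            (1 - pc[1]) * prof$genes$glia) +
      pc[2] * prof$genes$contaminant
    expect_equal(unname(aw), ref)
  }
  expect_error(mixture_abundance(prof, 0.5, 1.2, 1), "fractions")
})

test_that("count simulation matches the NB model moments", {
  a <- c(g1 = 1, g2 = 3, g3 = 6)
  # alpha = 0: Poisson; sample mean of mu = 1000 within 5 s.e. (200 reps)
  reps <- vapply(1:200, function(i)
    simulate_counts(a, 10000, 0, seed = i)[["g1"]], numeric(1))
  mu <- 1000
  expect_lt(abs(mean(reps) - mu), 5 * sqrt(mu / 200))
  # fixed seed -> identical draws
  expect_identical(simulate_counts(a, 5000, 0.1, seed = 42),
                   simulate_counts(a, 5000, 0.1, seed = 42))
  # variance/mean of a mu = 500, alpha = 0.1 gene over 2000 replicates
  ks <- vapply(1:2000, function(i)
    simulate_counts(c(g = 1), 500, 0.1, seed = 10000 + i)[["g"]], numeric(1))
  expect_lt(abs(var(ks) / mean(ks) - (1 + 0.1 * 500)), 0.2 * (1 + 0.1 * 500))
  expect_error(simulate_counts(a, 1000, -0.1), "alpha")
})

test_that("read simulation injects duplicates at the configured rate", {
  # pick an input whose duplicate fraction is exactly 0.5
  d_max <- 0.986; lambda <- 0.15
  input <- log(d_max / 0.5) / lambda
  libs <- sim_libraries(n_wt = 1, n_kd = 0, cdna_input = input)
  cfg <- simulation_config(n_genes = 25, library_size = 10000, seed = 31,
                           libraries = libs,
                           corrupt_rates = c(n_read = 0, homopolymer = 0,
                                             low_quality = 0, qual5p = 0))
  ann <- tq_annotation(); prof <- tq_profiles()
  counts <- simulate_counts(mixture_abundance(prof, 0.5, 0, 1), 10000, 0.02,
                            seed = 7)
  sim <- simulate_reads(counts, ann, cfg, library = libs[1, ], seed = 8)
  rate <- mean(sim$truth$category == "duplicate")
  expect_lt(abs(rate - 0.5), 0.02)
  # the duplicate fraction is monotone decreasing in cDNA input
  d <- d_max * exp(-lambda * c(2, 4, 6, 12))
  expect_true(all(diff(d) < 0))
})

test_that("unbiased reads show flat per-position composition", {
  cfg <- tq_config(bias_amplitude = 0,
                   corrupt_rates = c(n_read = 0, homopolymer = 0,
                                     low_quality = 0, qual5p = 0))
  counts <- simulate_counts(mixture_abundance(tq_profiles(), 0.5, 0, 1),
                            5000, 0.02, seed = 9)
  sim <- simulate_reads(counts, tq_annotation(), cfg,
                        library = cfg$libraries[1, ], seed = 10)
  prof <- nucleotide_profile(sim$reads, 25)
  expect_lt(bias_score(prof), 0.03)
  # and the configured bias is visible at the default amplitude
  cfgb <- tq_config(corrupt_rates = c(n_read = 0, homopolymer = 0,
                                      low_quality = 0, qual5p = 0))
  simb <- simulate_reads(counts, tq_annotation(), cfgb,
                         library = cfgb$libraries[1, ], seed = 10)
  expect_gt(bias_score(nucleotide_profile(simb$reads, 25)),
            3 * bias_score(prof))
})

test_that("full simulation emission is reproducible byte for byte", {
  cfg <- simulation_config(n_genes = 12, library_size = 400, seed = 77,
                           libraries = sim_libraries(n_wt = 1, n_kd = 1,
                                                     cdna_input = c(4, 6)))
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})
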