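#' Library sheet for a simulated experiment
#'
#' Builds the per-library design table used by [simulation_config()]: one row
#' per sequencing library with its group label, contaminant-tissue fraction,
#' nominal cDNA input and driver-transgene scaling.
#'
#' @param n_wt,n_kd Number of control ("WT") and knockdown ("KD") libraries.
#' @param contamination Contaminant-tissue fraction `c` per library, recycled;
#'   each value in `[0, 1)`.
#' @param cdna_input Nominal cDNA input (ng) per library, recycled. Drives the
#'   injected PCR-duplicate rate (lower input, more duplicates).
#' @param transgene_scale Multiplier on the driver transgene's abundance per
#'   library (1 = nominal; small values emulate weak driver expression).
#' @return A `data.frame` with columns `label`, `group`, `contamination`,
#'   `cdna_input`, `transgene_scale`.
#' @export
sim_libraries <- function(n_wt = 3, n_kd = 3,
                          contamination = 0,
                          cdna_input = c(2, 4, 6, 3, 5, 6),
                          transgene_scale = 1) {
  n <- n_wt + n_kd
  data.frame(
    label = c(sprintf("WT_%d", seq_len(n_wt)), sprintf("KD_%d", seq_len(n_kd))),
    group = rep(c("WT", "KD"), c(n_wt, n_kd)),
    contamination = rep_len(contamination, n),
    cdna_input = rep_len(cdna_input, n),
    transgene_scale = rep_len(transgene_scale, n),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic mixed-tissue experiment
#'
#' Collects every knob of the generator: gene content, the two-cell-type
#' mixture of the target tissue, the cell-type-restricted knockdown, the
#' contaminant tissue admixture, count noise, and the read-level artifacts
#' (5' composition bias, PCR duplicates, QC-failing read classes, optional
#' shRNA transgene reads).
#'
#' The target tissue is a mix of neuron-like cells (fraction `phi`) and
#' glia-like cells (`1 - phi`). The knockdown multiplies the target gene's
#' abundance by `knockdown_ratio` in neuron-like cells only (the driver is
#' neuron-restricted); `somatic_knockdown = TRUE` applies it in every
#' compartment instead, emulating a whole-animal deficiency. A physically
#' adjacent contaminant tissue is mixed in at the per-library fraction given
#' in `libraries$contamination`.
#'
#' @param n_genes Number of endogenous genes (>= 10); a driver transgene on
#'   its own reference is added on top.
#' @param class_proportions Named fractions for gene classes `neuronal`,
#'   `glial`, `contaminant_specific`, `ubiquitous`; must sum to 1.
#' @param phi Fraction of neuron-like cells in the target tissue, in (0, 1).
#' @param knockdown_ratio Residual target-gene expression `r` in knockdown
#'   cells, in `[0, 1]` (1 = no knockdown).
#' @param somatic_knockdown Apply the knockdown in all compartments rather
#'   than neuron-like cells only.
#' @param libraries Library sheet, see [sim_libraries()].
#' @param dispersion Negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2). The default 0.02 reflects libraries made
#'   from pools of hundreds of dissected animals, which averages away most
#'   biological variability.
#' @param library_size Expected fragments per library.
#' @param read_length Bases per mate (> 10).
#' @param fragment_length Range (min, max) of fragment lengths; fragments are
#'   drawn uniformly within it (mean 300 by default, matching random-primed
#'   fragmentation to ~300 bp).
#' @param bias_amplitude Strength of the 5' composition bias over the first
#'   `bias_positions` sequencing cycles (0 = unbiased).
#' @param bias_positions Number of leading cycles affected by the bias.
#' @param bias_profile Optional 4 x `bias_positions` matrix (rows A, C, G, T)
#'   of per-position composition multipliers; built from `bias_amplitude`
#'   when `NULL`.
#' @param corrupt_rates Named fractions (relative to the library's fragment
#'   count) of injected QC-failing read pairs: `n_read` (contains an 'N'),
#'   `homopolymer` (a >= 50 nt single-base run), `low_quality` (mean Phred
#'   < 30), and `qual5p` (low-quality first 10 cycles, rescued by 5'
#'   trimming).
#' @param duplicate_d_max,duplicate_lambda PCR-duplicate model: the injected
#'   duplicate fraction is `d_max * exp(-lambda * cdna_input)`, monotone
#'   decreasing in input. Defaults place inputs of 2--6 ng at duplicate
#'   rates ~0.73--0.40.
#' @param shrna_rate Fraction (relative to fragment count) of double-stranded
#'   shRNA transgene read pairs injected into knockdown libraries, drawn in
#'   both orientations from the 3' targeted half of the target gene.
#' @param response_fraction Fraction of genes that respond transcriptionally
#'   to the knockdown (in compartments where it is active).
#' @param response_log2fc Magnitude of the responder effect at full knockdown
#'   (log2 scale; signs alternate).
#' @param seed Integer seed; the full simulation is byte-reproducible given
#'   the seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 60,
                              class_proportions = c(neuronal = 0.2,
                                                    glial = 0.1,
                                                    contaminant_specific = 0.2,
                                                    ubiquitous = 0.5),
                              phi = 0.5,
                              knockdown_ratio = 0.2,
                              somatic_knockdown = FALSE,
                              libraries = sim_libraries(),
                              dispersion = 0.02,
                              library_size = 20000,
                              read_length = 100,
                              fragment_length = c(200, 400),
                              bias_amplitude = 0.5,
                              bias_positions = 10,
                              bias_profile = NULL,
                              corrupt_rates = c(n_read = 0.01,
                                                homopolymer = 0.01,
                                                low_quality = 0.01,
                                                qual5p = 0.08),
                              duplicate_d_max = 0.986,
                              duplicate_lambda = 0.15,
                              shrna_rate = 0,
                              response_fraction = 0.3,
                              response_log2fc = 1,
                              seed = 1) {
  if (n_genes < 10) stopf("n_genes must be >= 10, got %s", n_genes)
  cls <- c("neuronal", "glial", "contaminant_specific", "ubiquitous")
  if (!setequal(names(class_proportions), cls))
    stopf("class_proportions must be named %s", paste(cls, collapse = ", "))
  class_proportions <- class_proportions[cls]
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-8)
    stopf("class_proportions must be non-negative and sum to 1")
  if (phi <= 0 || phi >= 1) stopf("phi must be in (0, 1)")
  if (knockdown_ratio < 0 || knockdown_ratio > 1)
    stopf("knockdown_ratio must be in [0, 1]")
  if (any(libraries$contamination < 0) || any(libraries$contamination >= 1))
    stopf("library contamination fractions must be in [0, 1)")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (library_size <= 0) stopf("library_size must be > 0")
  if (read_length <= 10) stopf("read_length must be > 10")
  if (length(fragment_length) != 2 || fragment_length[1] > fragment_length[2])
    stopf("fragment_length must be (min, max)")
  if (fragment_length[1] < read_length)
    stopf("minimum fragment length must be >= read_length")
  if (any(corrupt_rates < 0) || any(corrupt_rates > 1))
    stopf("corrupt_rates must be fractions")
  if (is.null(bias_profile))
    bias_profile <- default_bias_profile(bias_amplitude, bias_positions)
  if (!is.matrix(bias_profile) || nrow(bias_profile) != 4)
    stopf("bias_profile must be a 4-row matrix (A, C, G, T)")
  structure(list(
    n_genes = as.integer(n_genes),
    class_proportions = class_proportions,
    phi = phi,
    knockdown_ratio = knockdown_ratio,
    somatic_knockdown = isTRUE(somatic_knockdown),
    libraries = libraries,
    dispersion = dispersion,
    library_size = as.integer(library_size),
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    bias_amplitude = bias_amplitude,
    bias_positions = as.integer(bias_positions),
    bias_profile = bias_profile,
    corrupt_rates = corrupt_rates,
    duplicate_d_max = duplicate_d_max,
    duplicate_lambda = duplicate_lambda,
    shrna_rate = shrna_rate,
    response_fraction = response_fraction,
    response_log2fc = response_log2fc,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed, deterministic wiggle over the first `p` cycles: multiplicative
# composition weights per base and position. Amplitude 0 gives all-ones
# (no bias).
default_bias_profile <- function(amplitude, p = 10) {
  m <- outer(1:4, seq_len(p), function(b, pos) {
    exp(amplitude * sin(1.7 * pos + 2.1 * b))
  })
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mixed-tissue experiment configuration\n")
  cat(sprintf("  genes: %d (+1 transgene)   phi: %.2f   knockdown ratio: %.2f (%s)\n",
              x$n_genes, x$phi, x$knockdown_ratio,
              if (x$somatic_knockdown) "somatic" else "neuron-restricted"))
  cat(sprintf("  libraries: %d (%s)\n", nrow(x$libraries),
              paste(sprintf("%s c=%.2g", x$libraries$label,
                            x$libraries$contamination), collapse = ", ")))
  cat(sprintf("  library size: %d   dispersion: %.3g   read length: %d   seed: %d\n",
              x$library_size, x$dispersion, x$read_length, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' @param config A `sim_config` object.
#' @param path File path.
#' @return `read_config()` returns a `sim_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$bias_profile <- NULL  # reconstructed from amplitude on read
  # named vectors must survive as JSON objects
  x$class_proportions <- as.list(x$class_proportions)
  x$corrupt_rates <- as.list(x$corrupt_rates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$libraries <- as.data.frame(x$libraries, stringsAsFactors = FALSE)
  x$class_proportions <- unlist(x$class_proportions)
  x$corrupt_rates <- unlist(x$corrupt_rates)
  do.call(simulation_config, x)
}
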