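#' Per-compartment baseline expression profiles
#'
#' Assigns each gene a class (`neuronal`, `glial`, `contaminant_specific`,
#' `ubiquitous`) and a baseline abundance in each of the three cellular
#' compartments of the simulation: neuron-like cells of the target tissue,
#' glia-like cells of the target tissue, and the adjacent contaminant
#' tissue. Abundances are in arbitrary transcript-per-cell units;
#' ubiquitous genes have identical abundance in every compartment and the
#' three cell-type-restricted blocks are scaled to a common total, so the
#' compartments carry comparable overall signal and linear tissue mixtures
#' stay on a common scale.
#'
#' Marker genes are chosen to mirror the classic driver-line panel: a
#' neuron-restricted marker (elav-like), a glia-restricted marker
#' (repo-like), a contaminant-tissue marker (pendulin-like, expressed ~100x
#' higher in the contaminant tissue than in the target tissue), a
#' ubiquitous control (Usp7-like), the ubiquitously expressed knockdown
#' target (Smn-like), and the driver transgene (GAL4-like), which is
#' expressed in neuron-like cells only and lives on its own reference.
#'
#' A configurable fraction of non-marker genes are "responders": their
#' abundance shifts by `response_log2fc` (alternating sign) in any
#' compartment where the target-gene knockdown is active, emulating the
#' downstream transcriptome response that differential expression is meant
#' to detect.
#'
#' @param config A [simulation_config()].
#' @param annotation The matching [build_annotation()] output.
#' @return An object of class `tissue_profiles`: list with `genes`
#'   (data.frame `gene_id`, `class`, `neuron`, `glia`, `contaminant`,
#'   `response_beta`) and `markers` (named list of role -> gene id).
#' @export
build_profiles <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "annotation"))
  with_seed(config$seed + 1L, {
    ids <- setdiff(annotation$genes$gene_id, "transgene")
    n <- length(ids)
    counts <- floor(config$class_proportions * n)
    while (sum(counts) < n) {
      i <- which.max(config$class_proportions * n - counts)
      counts[i] <- counts[i] + 1L
    }
    # the knockdown target is pinned to the dedicated single-exon first
    # gene: ubiquitously and strongly expressed, like the genuine target;
    # the remaining genes are shuffled across the class quotas
    counts["ubiquitous"] <- max(counts[["ubiquitous"]] - 1L, 0L)
    while (sum(counts) < n - 1L) counts["ubiquitous"] <- counts[["ubiquitous"]] + 1L
    while (sum(counts) > n - 1L) {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
    }
    class <- c("ubiquitous", sample(rep(names(counts), counts)))
    x <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)
    x[1] <- stats::quantile(x, 0.8)
    # scale the three cell-type-restricted blocks to one common total so
    # the compartments carry comparable signal mass; ubiquitous genes keep
    # identical per-cell abundance in every compartment, which makes the
    # bulk knockdown fold change exactly phi * r + (1 - phi)
    blocks <- c("neuronal", "glial", "contaminant_specific")
    bsum <- vapply(blocks, function(b) sum(x[class == b]), numeric(1))
    target_total <- mean(bsum)
    for (b in blocks) x[class == b] <- x[class == b] * target_total / bsum[[b]]
    neuron <- glia <- contaminant <- numeric(n)
    neuron[class == "neuronal"] <- x[class == "neuronal"]
    glia[class == "glial"] <- x[class == "glial"]
    cs <- class == "contaminant_specific"
    contaminant[cs] <- x[cs]
    neuron[cs] <- glia[cs] <- 0.01 * x[cs]  # contaminant genes barely on in target
    ub <- class == "ubiquitous"
    neuron[ub] <- glia[ub] <- contaminant[ub] <- x[ub]

    top <- function(cl, rank = 1) ids[cl][order(x[cl], decreasing = TRUE)][rank]
    markers <- list(
      neuron_marker = top(class == "neuronal"),
      glia_marker = top(class == "glial"),
      contaminant_marker = top(class == "contaminant_specific"),
      knockdown_target = ids[1],
      ubiquitous_control = top(ub & ids != ids[1], 1),
      transgene = "transgene")

    responders <- setdiff(ids, unlist(markers))
    n_resp <- round(config$response_fraction * n)
    responders <- sample(responders, min(n_resp, length(responders)))
    beta <- stats::setNames(numeric(n), ids)
    if (length(responders))
      beta[responders] <- config$response_log2fc *
        rep_len(c(1, -1), length(responders))

    genes <- data.frame(
      gene_id = c(ids, "transgene"),
      class = c(class, "transgene"),
      neuron = c(neuron, stats::quantile(x, 0.9)),  # strong pan-neuronal driver
      glia = c(glia, 0),
      contaminant = c(contaminant, 0),
      response_beta = c(beta, 0),
      stringsAsFactors = FALSE)
    rownames(genes) <- genes$gene_id
    structure(list(genes = genes, markers = markers),
              class = "tissue_profiles")
  })
}

#' @export
print.tissue_profiles <- function(x, ...) {
  cat("Tissue expression profiles:",
      sum(x$genes$class != "transgene"), "genes + transgene\n")
  cat("  classes:", paste(names(table(x$genes$class)),
                          table(x$genes$class), sep = "=", collapse = "  "), "\n")
  cat("  markers:", paste(names(x$markers), unlist(x$markers),
                          sep = "->", collapse = "  "), "\n")
  invisible(x)
}

#' Expected per-gene abundance of a mixed-tissue library
#'
#' The bulk expectation of the two-cell-type target tissue with contaminant
#' admixture: for gene g,
#' `a(g) = (1 - c) * (phi * neuron(g) * k(g) + (1 - phi) * glia(g)) +
#' c * contaminant(g)`, where `k(g) = r` for the knockdown target and 1
#' otherwise. With `somatic = TRUE` the knockdown factor (and the responder
#' shifts) apply in every compartment, not just neuron-like cells.
#' Responder genes are scaled by `2^(beta * (1 - r))` in compartments where
#' the knockdown is active.
#'
#' The vector is an expectation in arbitrary units; it is renormalized to
#' sum to 1 only at count-sampling time.
#'
#' @param profiles A [build_profiles()] object.
#' @param phi Neuron-like cell fraction of the target tissue.
#' @param c Contaminant-tissue fraction of the library, in `[0, 1)`.
#' @param r Residual target-gene expression in knockdown cells, `[0, 1]`.
#' @param somatic Apply the knockdown in all compartments.
#' @param transgene_scale Multiplier on the driver transgene abundance.
#' @return Named numeric vector of expected abundances.
#' @export
mixture_abundance <- function(profiles, phi, c, r, somatic = FALSE,
                              transgene_scale = 1) {
  stopifnot(inherits(profiles, "tissue_profiles"))
  if (phi < 0 || phi > 1 || c < 0 || c >= 1 || r < 0 || r > 1)
    stopf("fractions out of range: phi=%s c=%s r=%s", phi, c, r)
  g <- profiles$genes
  kd <- function(v) {
    v <- v * ifelse(g$gene_id == profiles$markers$knockdown_target, r, 1)
    v * 2^(g$response_beta * (1 - r))
  }
  neuron <- kd(g$neuron)
  glia <- if (somatic) kd(g$glia) else g$glia
  cont <- if (somatic) kd(g$contaminant) else g$contaminant
  tg <- g$gene_id == "transgene"
  neuron[tg] <- neuron[tg] * transgene_scale
  a <- (1 - c) * (phi * neuron + (1 - phi) * glia) + c * cont
  stats::setNames(a, g$gene_id)
}
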