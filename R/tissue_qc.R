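#' Build a marker-gene panel
#'
#' The panel holds, per marker, its role, its expected (reference) FPKM in
#' the target tissue and in the contaminant tissue, and decision
#' thresholds. Roles mirror the driver-line marker logic: a
#' neuron-restricted and a glia-restricted target-tissue marker, the
#' driver transgene, a contaminant-tissue marker and a ubiquitous control.
#'
#' Default thresholds are relative to the target-tissue reference values:
#' a target-tissue marker triggers when observed FPKM drops below
#' `target_min_factor` times its reference, and the contaminant marker
#' when it exceeds `contaminant_max_factor` times its (low) target-tissue
#' reference. Under the linear signal-dilution model a marker falls to
#' `(1 - c)` of its reference at contaminant fraction `c`, so
#' `target_min_factor = 0.8` detects `c >= 0.3` with margin for count
#' noise while staying conservative at `c = 0` (the contaminant-marker
#' condition must fire jointly). The transgene threshold is resolved at
#' evaluation time as `transgene_min_factor` times the median transgene
#' FPKM of non-contaminated libraries.
#'
#' @param profiles [build_profiles()] output.
#' @param annotation Matching annotation (for union-exon lengths).
#' @param phi Neuron-like fraction used for the target-tissue reference.
#' @param target_min_factor,contaminant_max_factor,transgene_min_factor
#'   Threshold multipliers described above.
#' @return Data frame of class `marker_panel` with columns `gene_id`,
#'   `role`, `ref_target`, `ref_contaminant`, `min_fpkm`, `max_fpkm`.
#' @export
marker_panel <- function(profiles, annotation, phi = 0.5,
                         target_min_factor = 0.8,
                         contaminant_max_factor = 2,
                         transgene_min_factor = 0.5) {
  stopifnot(inherits(profiles, "tissue_profiles"))
  a_target <- mixture_abundance(profiles, phi, 0, 1)
  a_cont <- stats::setNames(profiles$genes$contaminant, profiles$genes$gene_id)
  len <- stats::setNames(annotation$genes$union_length, annotation$genes$gene_id)
  efpkm <- function(a, g) 1e9 * a[[g]] / sum(a) / len[[g]]
  mk <- profiles$markers
  rows <- list(
    c(gene = mk$neuron_marker, role = "target_tissue_neuron"),
    c(gene = mk$glia_marker, role = "target_tissue_glia"),
    c(gene = mk$transgene, role = "transgene"),
    c(gene = mk$contaminant_marker, role = "contaminant"),
    c(gene = mk$ubiquitous_control, role = "ubiquitous_control"))
  panel <- do.call(rbind, lapply(rows, function(r) {
    rt <- efpkm(a_target, r[["gene"]])
    rc <- efpkm(a_cont, r[["gene"]])
    data.frame(gene_id = r[["gene"]], role = r[["role"]],
               ref_target = rt, ref_contaminant = rc,
               min_fpkm = switch(r[["role"]],
                                 target_tissue_neuron = ,
                                 target_tissue_glia = target_min_factor * rt,
                                 transgene = NA_real_,  # dynamic
                                 NA_real_),
               max_fpkm = if (r[["role"]] == "contaminant")
                 contaminant_max_factor * rt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(panel, "transgene_min_factor") <- transgene_min_factor
  class(panel) <- c("marker_panel", "data.frame")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  roles <- panel$role
  if (!any(roles %in% c("target_tissue_neuron", "target_tissue_glia")))
    stopf("panel needs at least one target-tissue marker")
  if (!any(roles == "contaminant"))
    stopf("panel needs at least one contaminant marker")
  if (sum(roles == "transgene") != 1)
    stopf("panel needs exactly one transgene entry")
  thr <- c(panel$min_fpkm, panel$max_fpkm)
  if (any(!is.na(thr) & thr <= 0)) stopf("panel thresholds must be positive")
  invisible(panel)
}

#' Read or write a marker panel as JSON
#'
#' @param panel A [marker_panel()].
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(
    list(markers = as.data.frame(panel),
         transgene_min_factor = attr(panel, "transgene_min_factor") %||% 0.5),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel <- as.data.frame(x$markers, stringsAsFactors = FALSE)
  attr(panel, "transgene_min_factor") <- x$transgene_min_factor %||% 0.5
  class(panel) <- c("marker_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Flag contaminated and low-transgene libraries with the marker panel
#'
#' A library is `contaminated` when every contaminant marker exceeds its
#' maximal FPKM threshold *and* at least one target-tissue marker falls
#' below its minimal threshold — the joint pattern of neighboring-tissue
#' admixture. A non-contaminated library is `low_transgene` when the
#' driver transgene's FPKM falls below its threshold (resolved as a
#' fraction of the median transgene FPKM among non-contaminated
#' libraries when not fixed in the panel). `pass` means neither flag. The
#' contamination score is
#' `log2((1 + mean contaminant FPKM) / (1 + mean target-tissue marker
#' FPKM))`; larger is worse.
#'
#' @param fpkm_mat Genes x libraries FPKM matrix; all panel genes must be
#'   present, except the transgene which is treated as FPKM 0 when absent
#'   (a transgene quantified against its own reference that attracts no
#'   reads is a meaningful zero).
#' @param panel A [marker_panel()].
#' @return Data frame of class `library_verdicts`: `library`,
#'   `contaminated`, `low_transgene`, `pass`, `score`, with per-marker
#'   observations in attribute `details`.
#' @export
evaluate_panel <- function(fpkm_mat, panel) {
  validate_panel(panel)
  if (nrow(panel) == 0) stopf("empty panel")
  libs <- colnames(fpkm_mat) %||% as.character(seq_len(ncol(fpkm_mat)))
  obs <- function(g) {
    if (g %in% rownames(fpkm_mat)) fpkm_mat[g, ]
    else if (panel$role[panel$gene_id == g] == "transgene") rep(0, ncol(fpkm_mat))
    else stopf("panel gene '%s' missing from the FPKM matrix", g)
  }
  O <- do.call(rbind, lapply(panel$gene_id, function(g) as.numeric(obs(g))))
  dimnames(O) <- list(panel$gene_id, libs)
  is_target <- panel$role %in% c("target_tissue_neuron", "target_tissue_glia")
  is_cont <- panel$role == "contaminant"
  is_tg <- panel$role == "transgene"
  cont_hi <- apply(O[is_cont, , drop = FALSE] >
                     panel$max_fpkm[is_cont], 2, all)
  target_lo <- apply(O[is_target, , drop = FALSE] <
                       panel$min_fpkm[is_target], 2, any)
  contaminated <- cont_hi & target_lo
  tg_min <- panel$min_fpkm[is_tg]
  if (is.na(tg_min)) {
    conf <- O[is_tg, !contaminated]
    tg_min <- (attr(panel, "transgene_min_factor") %||% 0.5) *
      (if (length(conf)) median(conf) else 0)
  }
  low_transgene <- !contaminated & (O[is_tg, ] < tg_min)
  score <- log2((1 + colMeans(O[is_cont, , drop = FALSE])) /
                  (1 + colMeans(O[is_target, , drop = FALSE])))
  out <- data.frame(library = libs, contaminated = contaminated,
                    low_transgene = low_transgene,
                    pass = !contaminated & !low_transgene,
                    score = score, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "details") <- data.frame(
    gene_id = rep(panel$gene_id, ncol(O)),
    role = rep(panel$role, ncol(O)),
    library = rep(libs, each = nrow(panel)),
    fpkm = as.vector(O),
    min_fpkm = rep(ifelse(is_tg, tg_min, panel$min_fpkm), ncol(O)),
    max_fpkm = rep(panel$max_fpkm, ncol(O)),
    stringsAsFactors = FALSE)
  class(out) <- c("library_verdicts", "data.frame")
  out
}

#' @export
print.library_verdicts <- function(x, ...) {
  cat("Marker-panel library verdicts:\n")
  print(as.data.frame(x))
  cat(sprintf("  pass: %d / %d\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' Estimate the contaminant-tissue fraction of a library
#'
#' Under the linear mixing model the contaminant marker's FPKM
#' interpolates between its target-tissue and contaminant-tissue reference
#' values, so
#' `c_hat = clamp01((observed - ref_target) / (ref_contaminant -
#' ref_target))`.
#'
#' @param observed Observed contaminant-marker FPKM (vector over
#'   libraries).
#' @param panel A [marker_panel()]; the first `contaminant` row is used.
#' @return Estimated contaminant fractions in `[0, 1]`.
#' @export
estimate_contamination <- function(observed, panel) {
  row <- panel[panel$role == "contaminant", ][1, ]
  if (is.na(row$gene_id)) stopf("panel has no contaminant marker")
  if (row$ref_contaminant <= row$ref_target)
    stopf("contaminant reference must exceed target reference")
  pmin(1, pmax(0, (observed - row$ref_target) /
                 (row$ref_contaminant - row$ref_target)))
}

#' Drop flagged libraries from a count matrix
#'
#' Retains only `pass` libraries and logs every exclusion with its flag
#' and contamination score. Refuses to leave any group with fewer than two
#' libraries (downstream differential expression needs replication).
#'
#' @param verdicts [evaluate_panel()] output; `verdicts$library` must match
#'   the count matrix column names.
#' @param counts A `count_matrix` or genes x libraries matrix.
#' @param groups Per-library group labels (taken from the `count_matrix`
#'   when omitted).
#' @return The filtered object of the same type, with the exclusion log as
#'   attribute `exclusions`.
#' @export
select_libraries <- function(verdicts, counts, groups = NULL) {
  is_cm <- inherits(counts, "count_matrix")
  mat <- if (is_cm) counts$counts else counts
  if (is.null(groups) && is_cm) groups <- counts$libraries$group
  keep <- verdicts$library[verdicts$pass]
  miss <- setdiff(verdicts$library, colnames(mat))
  if (length(miss)) stopf("verdict libraries missing from counts: %s",
                          paste(miss, collapse = ", "))
  if (!is.null(groups)) {
    gk <- groups[match(keep, colnames(mat))]
    short <- names(which(table(factor(gk, unique(groups))) < 2))
    if (length(short))
      stopf("group '%s' left with fewer than 2 libraries after selection",
            short[1])
  }
  excl <- verdicts[!verdicts$pass, c("library", "contaminated",
                                     "low_transgene", "score")]
  if (is_cm) {
    sel <- counts$libraries$label %in% keep
    out <- counts
    out$counts <- mat[, colnames(mat) %in% keep, drop = FALSE]
    out$libraries <- counts$libraries[sel, ]
  } else {
    out <- mat[, colnames(mat) %in% keep, drop = FALSE]
  }
  attr(out, "exclusions") <- excl
  out
}
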