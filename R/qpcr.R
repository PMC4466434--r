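# ChIP-qPCR double-ratio fold enrichment and relative mRNA levels.

#' A qPCR plate of Ct values
#'
#' Ct values keyed by locus and sample fraction (`"chip"` or `"input"`),
#' with per-locus amplification efficiency and a reference (control) locus
#' used for normalization. Technical replicates may appear as repeated
#' (locus, fraction) rows.
#'
#' @param ct `data.frame(locus, fraction, ct)` with optional `replicate`
#'   column; `ct` finite and `> 0`, `fraction` in `"chip"`, `"input"`.
#' @param efficiency Single value or named per-locus vector in `(1, 2]`
#'   (default 2, the ideal doubling-per-cycle convention).
#' @param reference Reference locus id (default `"yhaX"`, a low-conflict
#'   control region).
#' @return An object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(ct, efficiency = 2, reference = "yhaX") {
  if (!all(c("locus", "fraction", "ct") %in% names(ct)))
    stop("ct needs columns locus, fraction, ct", call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  if (!all(ct$fraction %in% c("chip", "input")))
    stop("fraction must be 'chip' or 'input'", call. = FALSE)
  if (any(efficiency <= 1 | efficiency > 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  if (!"replicate" %in% names(ct)) ct$replicate <- 1L
  structure(list(ct = ct, efficiency = efficiency, reference = reference),
            class = "qpcr_plate")
}

#' Read a qPCR plate from delimited text
#'
#' Expects columns `locus`, `fraction`, `ct` (optionally `replicate`);
#' delimiter sniffed from the extension (`.csv` comma, otherwise tab).
#'
#' @param path File path.
#' @param ... Passed to [qpcr_plate()] (`efficiency`, `reference`).
#' @export
read_qpcr_plate <- function(path, ...) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  qpcr_plate(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE), ...)
}

locus_efficiency <- function(plate, locus) {
  E <- plate$efficiency
  if (length(E) == 1L && is.null(names(E))) return(E)
  if (!locus %in% names(E))
    stop("no efficiency for locus ", locus, call. = FALSE)
  E[[locus]]
}

#' Relative template abundance from a Ct value
#'
#' `E^(-Ct)`: the standard inverse of exponential amplification, positive
#' and strictly decreasing in Ct.
#'
#' @param ct Quantification cycle(s).
#' @param efficiency Amplification efficiency in `(1, 2]`.
#' @export
abundance <- function(ct, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  efficiency ^ (-ct)
}

plate_ct <- function(plate, locus, fraction, replicate = NULL) {
  d <- plate$ct
  rows <- d$locus == locus & d$fraction == fraction
  if (!is.null(replicate)) rows <- rows & d$replicate == replicate
  if (!any(rows))
    stop("incomplete plate: no Ct for (", locus, ", ", fraction, ")",
         call. = FALSE)
  d$ct[rows]
}

#' ChIP-qPCR double-ratio fold enrichment
#'
#' Fold enrichment of a test locus over the reference locus:
#' `(test_chip / test_input) / (ref_chip / ref_input)` computed on
#' abundances. The reference locus as its own test returns exactly 1, and
#' any constant shift of all Ct values on the plate cancels. Technical
#' replicates are reduced either by averaging T values on the Ct scale
#' before conversion (`reduce = "ct"`, default) or by computing the fold
#' per replicate and averaging the folds (`reduce = "fold"`; requires a
#' `replicate` column pairing the four wells of each replicate).
#'
#' @param plate A [qpcr_plate()].
#' @param test_locus Locus id to test.
#' @param reduce `"ct"` or `"fold"`.
#' @return A single fold-enrichment value.
#' @export
fold_enrichment <- function(plate, test_locus, reduce = c("ct", "fold")) {
  reduce <- match.arg(reduce)
  ref <- plate$reference
  Et <- locus_efficiency(plate, test_locus)
  Er <- locus_efficiency(plate, ref)
  one_fold <- function(replicate = NULL) {
    tc <- mean(plate_ct(plate, test_locus, "chip", replicate))
    ti <- mean(plate_ct(plate, test_locus, "input", replicate))
    rc <- mean(plate_ct(plate, ref, "chip", replicate))
    ri <- mean(plate_ct(plate, ref, "input", replicate))
    (abundance(tc, Et) / abundance(ti, Et)) /
      (abundance(rc, Er) / abundance(ri, Er))
  }
  if (reduce == "ct") return(one_fold())
  reps <- sort(unique(plate$ct$replicate))
  mean(vapply(reps, function(r) one_fold(r), numeric(1)))
}

#' Relative mRNA level from RT-qPCR Ct values
#'
#' `E^(ct_reference - ct_gene)`: expression of a gene relative to a control
#' gene.
#'
#' @param ct_gene,ct_reference Ct values (replicates are averaged).
#' @param efficiency Amplification efficiency in `(1, 2]`.
#' @export
relative_mrna <- function(ct_gene, ct_reference, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  efficiency ^ (mean(ct_reference) - mean(ct_gene))
}
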