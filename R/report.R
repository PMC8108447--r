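# Cohort-level summaries: printed-fraction formatting, the subcellular
# qPCR enrichment formula, and count transforms.

#' Format a count fraction the way results are printed
#'
#' Percentages below 10 render with one decimal place, otherwise to the
#' nearest integer, both rounding half up. The stored counts stay exact;
#' this is purely a presentation rule.
#'
#' @param numerator,denominator Non-negative integers with
#'   `numerator <= denominator` and `denominator >= 1`.
#' @return List with `ratio` ("n/d"), `percent` ("X%"), `display`
#'   ("n/d (X%)") and the unrounded `value`.
#' @export
format_percent <- function(numerator, denominator) {
  if (denominator < 1L) stop("denominator must be >= 1")
  if (numerator < 0L || numerator > denominator)
    stop("require 0 <= numerator <= denominator")
  v <- 100 * numerator / denominator
  pct <- if (v < 10) {
    sprintf("%.1f%%", floor(v * 10 + 0.5 + 1e-9) / 10)
  } else {
    sprintf("%d%%", as.integer(floor(v + 0.5 + 1e-9)))
  }
  list(ratio = sprintf("%d/%d", numerator, denominator), percent = pct,
       display = sprintf("%d/%d (%s)", numerator, denominator, pct),
       value = v)
}

#' Subcellular enrichment from qPCR cycle thresholds
#'
#' Nuclear enrichment is `2^(Ct_cytoplasm - Ct_nucleus)`; cytoplasmic
#' enrichment is its reciprocal. Ct values are used raw (not normalised
#' to housekeeping genes).
#'
#' @param ct_nuclear,ct_cytoplasmic Finite Ct values.
#' @param direction `"nuclear"` or `"cytoplasmic"`.
#' @return Fold enrichment.
#' @export
ct_enrichment <- function(ct_nuclear, ct_cytoplasmic,
                          direction = c("nuclear", "cytoplasmic")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(ct_nuclear), is.finite(ct_cytoplasmic))
  if (direction == "nuclear") 2^(ct_cytoplasmic - ct_nuclear)
  else 2^(ct_nuclear - ct_cytoplasmic)
}

#' Transform a count matrix to log2(CPM + 1)
#'
#' Plain counts-per-million per column followed by `log2(cpm + 1)`; no
#' between-sample normalisation is applied.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @return Matrix of the same shape.
#' @export
counts_to_logcpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size in column(s): ",
                           paste(which(libs == 0), collapse = ", "))
  cpm <- sweep(counts, 2L, libs, "/") * 1e6
  log2(cpm + 1)
}

#' Summarise a classified pseudogene transcript cohort
#'
#' Counts mirror the per-transcript definitions of the classifier,
#' feature and ORF stages. The near-full-length ORF threshold is a
#' parental-ORF fraction strictly greater than 0.9.
#'
#' @param classified data.frame from [classify_transcripts()].
#' @param features Optional data.frame keyed by `tx_id` with columns
#'   `polya_motif` and `cage_supported`.
#' @param orfs Optional data.frame keyed by `tx_id` with columns
#'   `aa_length` and `orf_fraction`.
#' @param dnds Optional summary list from [dnds_summary()].
#' @return List of counts, with formatted fractions (via
#'   [format_percent()]) where a denominator exists; junction-sharing is
#'   `"n/a"` when no transcript is multi-exonic.
#' @export
summarize_cohort <- function(classified, features = NULL, orfs = NULL,
                             dnds = NULL) {
  pg <- classified[classified$is_pseudogene_transcript, , drop = FALSE]
  indep <- pg[!is.na(pg$independence) & pg$independence == "independent", ,
              drop = FALSE]
  ind_sense <- indep[indep$orientation == "sense", , drop = FALSE]
  ind_anti <- indep[indep$orientation == "antisense", , drop = FALSE]
  join <- function(tbl, ids, col) {
    if (is.null(tbl)) return(NULL)
    if (!all(ids %in% tbl$tx_id))
      stop("id mismatch: ", sum(!ids %in% tbl$tx_id),
           " transcript(s) missing from ", col, " table")
    tbl[match(ids, tbl$tx_id), , drop = FALSE]
  }
  out <- list(
    n_transcripts = nrow(classified),
    n_pseudogene_transcripts = nrow(pg),
    n_pseudogenes_overlapped = length(unique(pg$assigned_gene_id)),
    n_independent_sense = nrow(ind_sense),
    n_independent_antisense = nrow(ind_anti),
    n_independent = nrow(indep))
  out$pct_antisense <- if (nrow(indep) > 0)
    format_percent(nrow(ind_anti), nrow(indep)) else NULL
  out$n_multi_exonic <- sum(ind_sense$multi_exonic)
  me <- ind_sense[ind_sense$multi_exonic, , drop = FALSE]
  out$n_sharing_junctions <- if (nrow(me) > 0) sum(me$shares_reference_junction)
  else "n/a"
  if (!is.null(features)) {
    fs <- join(features, ind_sense$tx_id, "features")
    out$n_polya_positive <- sum(fs$polya_motif != "none")
    out$pct_polya <- if (nrow(ind_sense) > 0)
      format_percent(out$n_polya_positive, nrow(ind_sense)) else NULL
    fi <- join(features, indep$tx_id, "features")
    out$n_cage_supported <- sum(fi$cage_supported)
    out$pct_cage <- if (nrow(indep) > 0)
      format_percent(out$n_cage_supported, nrow(indep)) else NULL
  }
  if (!is.null(orfs)) {
    oi <- join(orfs, ind_sense$tx_id, "orfs")
    out$n_orf_gt100 <- sum(oi$aa_length > 100, na.rm = TRUE)
    out$pct_orf_gt100 <- if (nrow(ind_sense) > 0)
      format_percent(out$n_orf_gt100, nrow(ind_sense)) else NULL
    out$n_orf_gt90pct_parent <- sum(oi$orf_fraction > 0.9, na.rm = TRUE)
  }
  if (!is.null(dnds)) out$dnds <- dnds
  out
}
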