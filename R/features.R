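# Per-transcript evidence features: transcription start site (TSS)
# support from CAGE peaks and signal, and polyadenylation-motif scanning
# near the 3' terminus.

POLYA_MOTIFS <- c("AATAAA", "ATTAAA")

#' Transcription start site of a transcript
#'
#' The 0-based genomic coordinate of the first transcribed base: the first
#' exon's start for plus-strand transcripts, the last exon's final base
#' for minus-strand transcripts.
#'
#' @param tx A [transcript_model()].
#' @return Integer genomic position.
#' @export
transcript_tss <- function(tx) {
  if (tx$strand == "+") min(tx$exons$start) else max(tx$exons$end) - 1L
}

#' CAGE support of a TSS
#'
#' Distance from the TSS to the nearest CAGE peak (zero when inside a
#' peak); the TSS is supported when the distance is within `window`
#' (boundary inclusive).
#'
#' @param chrom Chromosome of the TSS.
#' @param tss 0-based TSS position.
#' @param peaks An [interval_set()] of CAGE peaks.
#' @param window Support window in bases (default 100).
#' @return List with `tss`, `distance_to_peak` (possibly `Inf`) and
#'   `supported`.
#' @export
cage_support <- function(chrom, tss, peaks, window = 100L) {
  stopifnot(window >= 0L)
  d <- nearest_distance(chrom, tss, peaks)
  list(tss = tss, distance_to_peak = d, supported = is.finite(d) && d <= window)
}

#' CAGE signal meta-profile around TSSs
#'
#' Averages per-base CAGE signal in a window of `flank` bases either side
#' of each TSS, orienting minus-strand windows 5' to 3' (genomic
#' coordinates reversed), then bins the averaged profile. Missing signal
#' counts as zero; each bin holds the mean per-base signal across TSSs.
#'
#' @param tss_df data.frame with columns `chrom`, `tss`, `strand`.
#' @param signal data.frame of per-base coverage with columns `chrom`,
#'   `start`, `end`, `score` (as read by [read_bedgraph()]).
#' @param flank Half-window size in bases (default 500).
#' @param bin Bin width; must divide `2 * flank` (default 10).
#' @return Numeric vector of length `2 * flank / bin`, oriented 5' to 3',
#'   with the bin covering offset zero at position `flank / bin + 1`.
#' @export
cage_metaprofile <- function(tss_df, signal, flank = 500L, bin = 10L) {
  if ((2L * flank) %% bin != 0L) stop("bin must divide 2 * flank")
  n_bins <- 2L * flank / bin
  if (nrow(tss_df) == 0L) return(numeric(n_bins))
  acc <- numeric(2L * flank)
  for (i in seq_len(nrow(tss_df))) {
    chrom <- tss_df$chrom[i]; tss <- tss_df$tss[i]; strand <- tss_df$strand[i]
    win_start <- tss - flank; win_end <- tss + flank  # [win_start, win_end)
    v <- numeric(2L * flank)
    s <- signal[signal$chrom == chrom & signal$end > win_start &
                  signal$start < win_end, , drop = FALSE]
    if (nrow(s)) {
      for (k in seq_len(nrow(s))) {
        a <- max(s$start[k], win_start); b <- min(s$end[k], win_end)
        if (b > a) v[(a - win_start + 1L):(b - win_start)] <- s$score[k]
      }
    }
    if (strand == "-") v <- rev(v)
    acc <- acc + v
  }
  per_base <- acc / nrow(tss_df)
  vapply(seq_len(n_bins), function(b)
    mean(per_base[((b - 1L) * bin + 1L):(b * bin)]), numeric(1))
}

#' Scan for a canonical polyadenylation motif near the 3' terminus
#'
#' Extracts the genomic window of `window` bases ending at (and including)
#' the transcript's 3'-terminal base, read in transcript orientation, and
#' searches for the hexamers AATAAA and ATTAAA. The canonical AATAAA takes
#' precedence when both occur; among occurrences of a motif the one
#' closest to the 3' end is reported. The offset counts bases from the 3'
#' terminus back to the motif's last base (0 = the motif ends at the
#' terminal base).
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of chromosome sequences.
#' @param window Scan window in bases (default 100, minimum 6).
#' @return List with `motif` (`"AATAAA"`, `"ATTAAA"` or `"none"`) and
#'   `offset_from_3prime` (`NA` when no motif).
#' @export
polya_scan <- function(tx, genome, window = 100L) {
  stopifnot(window >= 6L)
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("genome lacks chromosome '", tx$chrom, "'")
  clen <- nchar(chrom_seq)
  if (tx$strand == "+") {
    end3 <- max(tx$exons$end)             # terminal base at end3 - 1
    a <- max(0L, end3 - window); b <- end3
    if (a > end3 - window)
      warning("polyA window clipped at chromosome start for '", tx$id, "'")
    win <- substring(chrom_seq, a + 1L, b)
  } else {
    start3 <- min(tx$exons$start)         # terminal base at start3
    a <- start3; b <- min(clen, start3 + window)
    if (b < start3 + window)
      warning("polyA window clipped at chromosome end for '", tx$id, "'")
    win <- revcomp(substring(chrom_seq, a + 1L, b))
  }
  w <- nchar(win)
  best_for <- function(motif) {
    hits <- gregexpr(motif, win, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NA_integer_)
    last_base <- max(hits) + 5L            # 1-based position of motif's last base
    w - last_base                          # offset from 3' end
  }
  off <- best_for("AATAAA")
  if (!is.na(off)) return(list(motif = "AATAAA", offset_from_3prime = off))
  off <- best_for("ATTAAA")
  if (!is.na(off)) return(list(motif = "ATTAAA", offset_from_3prime = off))
  list(motif = "none", offset_from_3prime = NA_integer_)
}
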