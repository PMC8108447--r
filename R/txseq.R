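# Transcript-coordinate helpers: splicing sequence out of a genome and
# mapping transcript offsets back to genomic positions.

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in genomic order and reverse-complements
#' for minus-strand transcripts, yielding the sequence in transcript
#' orientation.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return Nucleotide string in transcript orientation.
#' @export
tx_spliced_seq <- function(tx, genome) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("genome lacks chromosome '", tx$chrom, "'")
  parts <- substring(chrom_seq, tx$exons$start + 1L, tx$exons$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

#' Map transcript offsets to genomic positions
#'
#' @param tx A [transcript_model()].
#' @param offsets 0-based offsets into the spliced transcript sequence.
#' @return Integer vector of 0-based genomic positions.
#' @export
tx_to_genome <- function(tx, offsets) {
  lens <- tx$exons$end - tx$exons$start
  total <- sum(lens)
  offsets <- as.integer(offsets)
  if (any(offsets < 0L | offsets >= total))
    stop("offset outside transcript of length ", total)
  if (tx$strand == "+") {
    cum <- cumsum(c(0L, lens))
    idx <- findInterval(offsets, cum, rightmost.closed = FALSE)
    tx$exons$start[idx] + (offsets - cum[idx])
  } else {
    # transcript position 0 is the last exon's final base
    lens_r <- rev(lens)
    starts_r <- rev(tx$exons$start)
    ends_r <- rev(tx$exons$end)
    cum <- cumsum(c(0L, lens_r))
    idx <- findInterval(offsets, cum, rightmost.closed = FALSE)
    ends_r[idx] - 1L - (offsets - cum[idx])
  }
}
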