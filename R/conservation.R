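# Ortholog location and codon-aware alignment: find the orthologous cDNA
# inside a flanked genomic window, align proteins globally, and thread the
# protein alignment back onto codons.

#' Extract a transcript's genomic span with flanks
#'
#' Returns the genomic span `[tx_start - flank, tx_end + flank)`, clipped
#' to the chromosome and oriented to the transcript strand.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank size in bases on each side (default 1000).
#' @return Nucleotide string in transcript orientation.
#' @export
extract_flanked_window <- function(tx, genome, flank = 1000L) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("genome lacks chromosome '", tx$chrom, "'")
  a <- min(tx$exons$start) - flank
  b <- max(tx$exons$end) + flank
  if (a < 0L || b > nchar(chrom_seq)) {
    message("flanked window for '", tx$id, "' clipped to chromosome bounds")
    a <- max(0L, a); b <- min(nchar(chrom_seq), b)
  }
  s <- substring(chrom_seq, a + 1L, b)
  if (tx$strand == "-") s <- revcomp(s)
  s
}

local_dna_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = TRUE)
}

#' Locate an orthologous cDNA within a genomic window
#'
#' Splice-naive Smith-Waterman local alignment (match +2, mismatch -3,
#' gap opening -5, gap extension -2 per base). The caller must supply the
#' window in the correct orientation. Returns `NULL` when no positive-
#' scoring local alignment exists ("no ortholog found").
#'
#' @param cdna Query cDNA sequence.
#' @param window Target window sequence (e.g. from
#'   [extract_flanked_window()] of an orthologous locus).
#' @return `NULL`, or a list with `query_span` and `target_span` (0-based
#'   half-open), `score`, and `aligned_target_subseq` (gaps removed).
#' @export
locate_ortholog_cdna <- function(cdna, window) {
  if (!nzchar(cdna) || !nzchar(window)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = toupper(cdna), subject = toupper(window), type = "local",
    substitutionMatrix = local_dna_matrix(),
    gapOpening = 5, gapExtension = 2)
  if (Biostrings::score(pa) <= 0) return(NULL)
  qs <- IRanges::start(Biostrings::pattern(pa))
  qe <- IRanges::end(Biostrings::pattern(pa))
  ts <- IRanges::start(Biostrings::subject(pa))
  te <- IRanges::end(Biostrings::subject(pa))
  sub <- gsub("-", "", as.character(Biostrings::subject(pa)), fixed = TRUE)
  list(query_span = c(qs - 1L, qe), target_span = c(ts - 1L, te),
       score = Biostrings::score(pa), aligned_target_subseq = sub)
}

#' Is a sequence length divisible by three?
#'
#' @param seq Nucleotide string.
#' @return Logical.
#' @export
check_divisible_by_three <- function(seq) {
  nchar(seq) %% 3L == 0L
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global protein alignment
#'
#' Needleman-Wunsch with BLOSUM62 and affine gaps (opening -11, extension
#' -1 per gap position); end gaps are penalised. A gap of length L costs
#' 11 + L.
#'
#' @param p1,p2 Amino-acid strings without gap characters.
#' @return List with `rows` (two gapped strings of equal length) and
#'   `score`.
#' @export
global_protein_align <- function(p1, p2) {
  if (!nzchar(p1) || !nzchar(p2)) stop("proteins must be non-empty")
  if (grepl("-", p1, fixed = TRUE) || grepl("-", p2, fixed = TRUE))
    stop("input proteins must not contain gap characters")
  pa <- Biostrings::pairwiseAlignment(
    pattern = p1, subject = p2, type = "global",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  r1 <- as.character(Biostrings::pattern(pa))
  r2 <- as.character(Biostrings::subject(pa))
  # the aligned views clip residues that sit against terminal gaps (the
  # score still includes the end-gap penalties); restore them explicitly
  ps <- IRanges::start(Biostrings::pattern(pa))
  pe <- IRanges::end(Biostrings::pattern(pa))
  ss <- IRanges::start(Biostrings::subject(pa))
  se <- IRanges::end(Biostrings::subject(pa))
  pre1 <- substring(p1, 1L, ps - 1L)
  pre2 <- substring(p2, 1L, ss - 1L)
  suf1 <- substring(p1, pe + 1L, nchar(p1))
  suf2 <- substring(p2, se + 1L, nchar(p2))
  row1 <- paste0(pre1, strrep("-", nchar(pre2)), r1,
                 suf1, strrep("-", nchar(suf2)))
  row2 <- paste0(strrep("-", nchar(pre1)), pre2, r2,
                 strrep("-", nchar(suf1)), suf2)
  list(rows = c(row1, row2), score = Biostrings::score(pa))
}

#' Thread a protein alignment back onto codons
#'
#' Expands each aligned amino-acid column to its source codon; gap columns
#' expand to `"---"`. Terminal stop codons must be stripped from the
#' cDNAs beforehand.
#'
#' @param aln A protein alignment from [global_protein_align()].
#' @param cdna1,cdna2 The coding sequences; `nchar(cdna_i)` must equal 3x
#'   the ungapped length of row i and translate to the degapped row.
#' @return List with `rows`: two gapped codon strings of equal length.
#' @export
thread_codons <- function(aln, cdna1, cdna2) {
  cdnas <- c(toupper(cdna1), toupper(cdna2))
  out <- vector("list", 2L)
  for (r in 1:2) {
    chars <- strsplit(aln$rows[r], "", fixed = TRUE)[[1]]
    ungapped <- sum(chars != "-")
    if (nchar(cdnas[r]) != 3L * ungapped)
      stop("cdna", r, " length ", nchar(cdnas[r]),
           " does not equal 3 x ungapped row length ", ungapped)
    prot <- translate_cdna(cdnas[r])
    k <- 0L
    cods <- character(length(chars))
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        cods[i] <- "---"
      } else {
        k <- k + 1L
        if (substring(prot, k, k) != chars[i])
          stop("cdna", r, " translation mismatch at codon ", k, ": '",
               substring(prot, k, k), "' vs aligned '", chars[i], "'")
        cods[i] <- substring(cdnas[r], 3L * k - 2L, 3L * k)
      }
    }
    out[[r]] <- paste(cods, collapse = "")
  }
  list(rows = c(out[[1]], out[[2]]))
}
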