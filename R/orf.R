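# ORF discovery in transcript sequences, parental-ORF fraction and
# gene-pseudogene fusion codon accounting.

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code; stop codons render `"*"`; codons containing a
#' non-ACGT base render `"X"`.
#'
#' @param cdna Nucleotide string with length divisible by 3.
#' @return Amino-acid string of length `nchar(cdna) / 3`.
#' @export
translate_cdna <- function(cdna) {
  cdna <- toupper(cdna)
  n <- nchar(cdna)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(cdna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans all three frames on the given strand only. An ORF runs from an
#' ATG to the first in-frame stop codon; the stop is required. The longest
#' ORF by amino-acid length is returned, ties resolved toward the
#' 5'-most start.
#'
#' @param tx_sequence Nucleotide string in transcript orientation.
#' @return List with `start_nt` (0-based offset), `end_nt` (exclusive,
#'   includes the stop codon), `aa_length` (excludes the stop), `protein`
#'   and `frame`; or `NULL` when no stop-terminated ORF exists.
#' @export
find_longest_orf <- function(tx_sequence) {
  s <- toupper(tx_sequence)
  n <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L  # 1-based codon starts
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    for (a in atg) {
      nxt <- stp[stp > a]
      if (!length(nxt)) next
      st <- nxt[1L]
      aa_len <- st - a            # codons ATG..(stop-1) inclusive
      start_nt <- frame + 3L * (a - 1L)
      end_nt <- frame + 3L * st
      if (is.null(best) || aa_len > best$aa_length ||
          (aa_len == best$aa_length && start_nt < best$start_nt)) {
        best <- list(start_nt = start_nt, end_nt = end_nt,
                     aa_length = aa_len,
                     protein = translate_cdna(substring(s, start_nt + 1L,
                                                        end_nt - 3L)),
                     frame = frame)
      }
    }
  }
  best
}

#' Does an ORF exceed an amino-acid length threshold?
#'
#' Strict inequality: an ORF of exactly `threshold_aa` residues does not
#' qualify.
#'
#' @param orf An ORF record from [find_longest_orf()] (or `NULL`).
#' @param threshold_aa Threshold in amino acids (default 100).
#' @return Logical.
#' @export
orf_exceeds <- function(orf, threshold_aa = 100L) {
  !is.null(orf) && orf$aa_length > threshold_aa
}

#' Fraction of the parental ORF length found intact
#'
#' Pure length ratio of the pseudogene ORF to the parent ORF, capped at 1;
#' transcripts without an ORF score 0.
#'
#' @param pseudo_orf ORF record from [find_longest_orf()] (or `NULL`).
#' @param parent_orf_aa Parent ORF length in amino acids (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
parent_orf_fraction <- function(pseudo_orf, parent_orf_aa) {
  if (parent_orf_aa < 1L) stop("parent_orf_aa must be >= 1")
  if (is.null(pseudo_orf)) return(0)
  min(1, pseudo_orf$aa_length / parent_orf_aa)
}

#' Detect gene-pseudogene fusion transcripts
#'
#' A fusion candidate is a transcript assigned to a protein-coding host
#' gene whose exons overlap a pseudogene retrocopy interval by at least
#' one base. Its longest ORF is computed on the spliced sequence, each
#' codon's three bases are mapped to genomic positions through the exon
#' chain, and a codon counts as pseudogene-derived when at least two of
#' its three bases fall inside the retrocopy interval.
#'
#' @param classified data.frame from [classify_transcripts()].
#' @param txs Named list of [transcript_model()] objects (by id).
#' @param genes Named list of [gene_model()] objects.
#' @param pg_records Named list of [pseudogene_record()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @return data.frame with columns `tx_id`, `host_gene_id`,
#'   `pseudogene_id`, `codons_from_pseudogene`,
#'   `pseudogene_strand_relative`; one row per (transcript, pseudogene)
#'   pair contributing at least one codon.
#' @export
detect_fusions <- function(classified, txs, genes, pg_records, genome) {
  if (length(genome) == 0L) stop("genome sequence required")
  empty <- data.frame(tx_id = character(), host_gene_id = character(),
                      pseudogene_id = character(),
                      codons_from_pseudogene = integer(),
                      pseudogene_strand_relative = character(),
                      stringsAsFactors = FALSE)
  hosts <- classified[classified$assigned_biotype == "protein_coding", ,
                      drop = FALSE]
  if (nrow(hosts) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(hosts))) {
    tx <- txs[[hosts$tx_id[i]]]
    overlapped <- Filter(function(rec) {
      ri <- rec$retro_interval
      exonic_overlap_bp(tx, interval_set(ri$chrom, ri$start, ri$end)) >= 1L
    }, pg_records)
    if (!length(overlapped)) next
    orf <- find_longest_orf(tx_spliced_seq(tx, genome))
    if (is.null(orf)) next
    cod_off <- seq(orf$start_nt, orf$end_nt - 3L, by = 3L)
    base_off <- as.vector(t(outer(cod_off, 0:2, `+`)))
    gpos <- tx_to_genome(tx, base_off)
    for (rec in overlapped) {
      ri <- rec$retro_interval
      inside <- tx$chrom == ri$chrom & gpos >= ri$start & gpos < ri$end
      per_codon <- colSums(matrix(inside, nrow = 3L))
      n_cod <- sum(per_codon >= 2L)
      if (n_cod >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          tx_id = tx$id, host_gene_id = hosts$assigned_gene_id[i],
          pseudogene_id = rec$gene$id,
          codons_from_pseudogene = n_cod,
          pseudogene_strand_relative =
            if (tx$strand == ri$strand) "sense" else "antisense",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
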