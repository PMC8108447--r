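# Domain containers. All coordinates are 0-based, half-open [start, end),
# the BED convention; GTF input/output is converted at the boundary.

#' Genomic interval
#'
#' A single 0-based half-open interval on a chromosome.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A list with class `"genomic_interval"`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot_scalar_chrom(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Transcript model
#'
#' An exon chain on one chromosome strand with an identifier and a
#' full-length read support count, as produced by long-read isoform
#' collapsing.
#'
#' @param id Transcript identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"` (never `"."`: transcripts are stranded).
#' @param exon_starts,exon_ends Parallel integer vectors of 0-based half-open
#'   exon coordinates, sorted by start and non-overlapping.
#' @param fl_read_count Non-negative full-length read support count.
#' @param sequence Optional spliced nucleotide sequence in transcript
#'   orientation.
#' @return A list with class `"transcript_model"`.
#' @export
transcript_model <- function(id, chrom, strand, exon_starts, exon_ends,
                             fl_read_count = 0L, sequence = NULL) {
  stopifnot_scalar_chrom(chrom)
  if (!strand %in% c("+", "-"))
    stop("transcript strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) == 0L || length(exon_starts) != length(exon_ends))
    stop("exon_starts and exon_ends must be parallel non-empty vectors")
  if (any(exon_starts < 0L) || any(exon_ends <= exon_starts))
    stop("exons must satisfy 0 <= start < end")
  if (is.unsorted(exon_starts, strictly = TRUE) && length(exon_starts) > 1L)
    stop("exons must be sorted by start")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("exons must be non-overlapping")
  fl_read_count <- as.integer(fl_read_count)
  if (is.na(fl_read_count) || fl_read_count < 0L)
    stop("fl_read_count must be a non-negative integer")
  structure(list(id = id, chrom = chrom, strand = strand,
                 exons = data.frame(start = exon_starts, end = exon_ends),
                 fl_read_count = fl_read_count, sequence = sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d(%s) %d exon(s), FL=%d\n",
              x$id, x$chrom, min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), x$fl_read_count))
  invisible(x)
}

BIOTYPES <- c("protein_coding", "processed_pseudogene",
              "unprocessed_pseudogene", "lncRNA", "other")

#' Gene model
#'
#' A reference gene with a biotype, its transcript models and (for coding
#' genes) the genomic CDS intervals.
#'
#' @param id,name Identifiers.
#' @param biotype One of `protein_coding`, `processed_pseudogene`,
#'   `unprocessed_pseudogene`, `lncRNA`, `other`.
#' @param transcripts List of [transcript_model()] objects.
#' @param cds Optional data.frame with columns `start`, `end` (0-based
#'   half-open genomic CDS intervals) lying within the exon union.
#' @return A list with class `"gene_model"`.
#' @export
gene_model <- function(id, name = id, biotype, transcripts = list(), cds = NULL) {
  if (!biotype %in% BIOTYPES)
    stop("unknown biotype '", biotype, "'")
  structure(list(id = id, name = name, biotype = biotype,
                 transcripts = transcripts, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) [%s] %d transcript(s)\n",
              x$id, x$name, x$biotype, length(x$transcripts)))
  invisible(x)
}

# All exons of a gene as a normalised interval set.
gene_exon_set <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, function(tx) {
    cbind(tx$exons, chrom = tx$chrom)
  }))
  if (is.null(ex) || nrow(ex) == 0L) stop("gene '", gene$id, "' has no exons")
  interval_set(ex$chrom, ex$start, ex$end)
}

# Genomic footprint [min start, max end) of a gene on its chromosome.
gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, function(tx) tx$exons))
  chrom <- gene$transcripts[[1]]$chrom
  genomic_interval(chrom, min(ex$start), max(ex$end),
                   gene$transcripts[[1]]$strand)
}

#' Pseudogene record
#'
#' A pseudogene gene model with its parent-gene linkage and the retrocopy
#' interval (the genomic footprint of the reinserted mRNA copy). The
#' record's strand is the retrocopy orientation, which equals the parent
#' mRNA orientation at the insertion site.
#'
#' @param gene A [gene_model()] with a pseudogene biotype.
#' @param parent_gene_id Identifier of the parent protein-coding gene.
#' @param retro_interval A [genomic_interval()] overlapping the pseudogene's
#'   exon union.
#' @return A list with class `"pseudogene_record"`.
#' @export
pseudogene_record <- function(gene, parent_gene_id, retro_interval) {
  if (!gene$biotype %in% c("processed_pseudogene", "unprocessed_pseudogene"))
    stop("pseudogene_record requires a pseudogene biotype")
  ex <- gene_exon_set(gene)
  ov <- sum(vapply(seq_len(nrow(ex)), function(i) {
    overlap_bp(genomic_interval(ex$chrom[i], ex$start[i], ex$end[i]),
               retro_interval)
  }, numeric(1)))
  if (ov < 1)
    stop("retro_interval must overlap the pseudogene's exon union")
  structure(list(gene = gene, parent_gene_id = parent_gene_id,
                 retro_interval = retro_interval),
            class = "pseudogene_record")
}

#' Length in amino acids of a gene's annotated ORF
#'
#' Sum of CDS interval lengths divided by three, minus one for the stop
#' codon.
#'
#' @param gene A coding [gene_model()] with a `cds` table.
#' @return Integer amino-acid length.
#' @export
parent_orf_length <- function(gene) {
  if (is.null(gene$cds) || nrow(gene$cds) == 0L)
    stop("gene '", gene$id, "' has no CDS annotation")
  nt <- sum(gene$cds$end - gene$cds$start)
  if (nt %% 3L != 0L)
    stop("CDS length of '", gene$id, "' is not divisible by 3")
  as.integer(nt / 3L - 1L)
}
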