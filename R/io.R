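# Readers/writers for the standard formats the pipeline touches. All
# coordinates are normalised to the internal 0-based half-open convention:
# GTF (1-based closed) is shifted on read/write, BED and bedGraph pass
# through unchanged.

IUPAC_DNA <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and RNA `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of nucleotide sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  out <- toupper(as.character(seqs))
  if (any(nchar(out) == 0L))
    stop("empty FASTA record: ", ids[nchar(out) == 0L][1L])
  for (i in seq_along(out)) {
    chars <- strsplit(out[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% IUPAC_DNA)
    if (length(bad))
      stop("non-IUPAC character '", chars[bad[1L]], "' in record '",
           ids[i], "' at position ", bad[1L])
  }
  out <- chartr("U", "T", out)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a Gencode-dialect GTF into gene models
#'
#' Accepts both `gene_type` and `gene_biotype` attribute keys. Printed
#' 1-based closed coordinates are converted to internal 0-based half-open
#' intervals; exons are grouped per transcript and sorted. Unknown biotypes
#' map to `"other"` with a warning.
#'
#' @param path Path to a GTF file with gene/transcript/exon/CDS features.
#' @return Named list of [gene_model()] objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L  # GTF printed start s -> internal s-1
  df$end0 <- df$end           # printed end == internal (exclusive) end
  bt_col <- if ("gene_type" %in% names(df)) "gene_type" else
    if ("gene_biotype" %in% names(df)) "gene_biotype" else
      stop("GTF lacks gene_type/gene_biotype attributes")
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("GTF contains no exon features")
  if (any(is.na(ex$transcript_id)))
    stop("exon feature without transcript_id")
  cds <- df[df$type == "CDS", , drop = FALSE]
  genes <- list()
  for (gid in unique(ex$gene_id)) {
    gex <- ex[ex$gene_id == gid, , drop = FALSE]
    bt <- as.character(gex[[bt_col]][1L])
    if (is.na(bt) || !bt %in% BIOTYPES) {
      warning("unknown biotype '", bt, "' for gene '", gid,
              "'; mapped to 'other'")
      bt <- "other"
    }
    txs <- lapply(unique(gex$transcript_id), function(tid) {
      tex <- gex[gex$transcript_id == tid, , drop = FALSE]
      if (length(unique(tex$seqnames)) > 1L)
        stop("transcript '", tid, "' spans multiple chromosomes")
      o <- order(tex$start0)
      transcript_model(id = tid, chrom = as.character(tex$seqnames[1L]),
                       strand = as.character(tex$strand[1L]),
                       exon_starts = tex$start0[o], exon_ends = tex$end0[o])
    })
    names(txs) <- unique(gex$transcript_id)
    gcds <- cds[cds$gene_id == gid, , drop = FALSE]
    cds_df <- NULL
    if (nrow(gcds)) {
      m <- interval_set(as.character(gcds$seqnames), gcds$start0, gcds$end0)
      cds_df <- data.frame(start = m$start, end = m$end)
    }
    gname <- if ("gene_name" %in% names(gex) && !is.na(gex$gene_name[1L]))
      as.character(gex$gene_name[1L]) else gid
    genes[[gid]] <- gene_model(id = gid, name = gname, biotype = bt,
                               transcripts = txs, cds = cds_df)
  }
  genes
}

#' Write gene models to GTF
#'
#' Emits gene, transcript, exon and CDS features in the Gencode attribute
#' dialect (`gene_id`, `transcript_id`, `gene_type`); internal 0-based
#' half-open coordinates are converted back to 1-based closed.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    span <- gene_span(g)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = span$chrom, start = span$start, end = span$end,
      strand = span$strand, type = "gene", gene_id = g$id,
      transcript_id = NA_character_, gene_type = g$biotype,
      gene_name = g$name)
    for (tx in g$transcripts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = min(tx$exons$start), end = max(tx$exons$end),
        strand = tx$strand, type = "transcript", gene_id = g$id,
        transcript_id = tx$id, gene_type = g$biotype, gene_name = g$name)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end,
        strand = tx$strand, type = "exon", gene_id = g$id,
        transcript_id = tx$id, gene_type = g$biotype, gene_name = g$name)
    }
    if (!is.null(g$cds) && nrow(g$cds)) {
      tx0 <- g$transcripts[[1L]]
      cds <- g$cds[order(g$cds$start), , drop = FALSE]
      ord <- if (tx0$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
      lens <- (cds$end - cds$start)[ord]
      phase <- integer(nrow(cds))
      phase[ord] <- (3L - (cumsum(c(0L, lens))[seq_along(lens)] %% 3L)) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx0$chrom, start = cds$start, end = cds$end,
        strand = tx0$strand, type = "CDS", gene_id = g$id,
        transcript_id = tx0$id, gene_type = g$biotype, gene_name = g$name,
        phase = phase)
    }
  }
  rows <- lapply(rows, function(r) {
    if (is.null(r$phase)) r$phase <- NA_integer_
    r
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, gene_id = df$gene_id, transcript_id = df$transcript_id,
    gene_type = df$gene_type, gene_name = df$gene_name, phase = df$phase)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a BED6 or BED12 file
#'
#' BED is already 0-based half-open, so coordinates pass through unshifted.
#' With `blocked = TRUE`, BED12 blocks are expanded into exon chains and a
#' list of [transcript_model()] is returned (the BED score column is taken
#' as the full-length read count); otherwise a plain data.frame of
#' intervals is returned.
#'
#' @param path Path to a BED file.
#' @param blocked Expand BED12 blocks into transcript models?
#' @return A list of transcript models, or a data.frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path, blocked = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) && any(GenomicRanges::start(gr) < 1L))
    stop("negative chromStart in BED file")
  if (!blocked) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = if (!is.null(gr$name)) gr$name else NA_character_,
                     score = if (!is.null(gr$score)) gr$score else NA_real_,
                     strand = as.character(GenomicRanges::strand(gr)))
    df$strand[df$strand == "*"] <- "."
    return(df)
  }
  if (is.null(gr$blocks))
    stop("BED12 with blocks required when blocked = TRUE")
  lapply(seq_along(gr), function(i) {
    chrom_start0 <- GenomicRanges::start(gr)[i] - 1L
    rel <- gr$blocks[[i]]  # 1-based relative to chromStart
    starts0 <- chrom_start0 + IRanges::start(rel) - 1L
    ends0 <- chrom_start0 + IRanges::end(rel)
    strand <- as.character(GenomicRanges::strand(gr))[i]
    transcript_model(
      id = gr$name[i], chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = strand, exon_starts = starts0, exon_ends = ends0,
      fl_read_count = if (!is.null(gr$score) && !is.na(gr$score[i]))
        as.integer(gr$score[i]) else 0L)
  })
}

#' Write transcript models to BED12
#'
#' @param txs List of [transcript_model()] objects.
#' @param path Output path.
#' @export
write_bed12 <- function(txs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(txs, function(t) t$chrom, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(txs, function(t) min(t$exons$start), integer(1)) + 1L,
      end = vapply(txs, function(t) max(t$exons$end), integer(1))),
    strand = vapply(txs, function(t) t$strand, character(1)))
  gr$name <- vapply(txs, function(t) t$id, character(1))
  gr$score <- vapply(txs, function(t) t$fl_read_count, integer(1))
  gr$blocks <- IRanges::IRangesList(lapply(txs, function(t) {
    off <- min(t$exons$start)
    IRanges::IRanges(start = t$exons$start - off + 1L, end = t$exons$end - off)
  }))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write intervals to BED6
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (`.` allowed).
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  strand <- ifelse(df$strand == ".", "*", df$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  gr$name <- df$name
  gr$score <- df$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a 4-column bedGraph of per-base signal
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score)
}

#' Write per-base signal to bedGraph
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  gr$score <- df$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a TSV report
#'
#' Header row, deterministic column order, UTF-8, one row per record.
#'
#' @param records A data.frame sharing one schema.
#' @param path Output path.
#' @export
write_tsv_report <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#'
#' @param path Path to a TSV file with a header row.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
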