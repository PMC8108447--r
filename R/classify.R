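# The central inference: which transcript models are pseudogene
# transcripts, whether they are independent of known genes, and their
# orientation relative to the parent gene.

#' Filter transcripts by full-length read support
#'
#' Keeps transcripts supported by at least `min_fl` full-length reads
#' (default two), preserving input order.
#'
#' @param txs List of [transcript_model()] objects.
#' @param min_fl Minimum full-length read count.
#' @return Filtered list.
#' @export
filter_by_support <- function(txs, min_fl = 2L) {
  Filter(function(tx) tx$fl_read_count >= min_fl, txs)
}

#' Assign a transcript to the gene model it best overlaps
#'
#' The gene with maximal exonic overlap (in bases, against the gene's
#' merged exon union) wins. Exact ties are broken by preferring a
#' pseudogene biotype, then the lexicographically smallest gene id.
#'
#' @param tx A [transcript_model()].
#' @param genes List of [gene_model()] objects.
#' @return List with `gene_id` (`"none"` when nothing overlaps) and
#'   `overlap_bp`.
#' @export
assign_transcript <- function(tx, genes) {
  if (length(genes) == 0L) return(list(gene_id = "none", overlap_bp = 0L))
  ov <- vapply(genes, function(g) exonic_overlap_bp(tx, gene_exon_set(g)),
               integer(1))
  ids <- vapply(genes, function(g) g$id, character(1))
  if (max(ov) == 0L) return(list(gene_id = "none", overlap_bp = 0L))
  best <- which(ov == max(ov))
  if (length(best) > 1L) {
    is_pg <- vapply(genes[best], function(g)
      g$biotype %in% c("processed_pseudogene", "unprocessed_pseudogene"),
      logical(1))
    if (any(is_pg)) best <- best[is_pg]
    best <- best[order(ids[best])][1L]
  }
  list(gene_id = ids[best], overlap_bp = ov[best])
}

#' Confirm that a transcript intersects a retrocopy track
#'
#' TRUE iff at least one exonic base overlaps the merged retrocopy
#' intervals, confirming the transcript covers the reinserted mRNA copy
#' itself rather than only flanking sequence.
#'
#' @param tx A [transcript_model()].
#' @param retro_track An [interval_set()] of retrocopy intervals.
#' @return Logical.
#' @export
confirm_retrocopy <- function(tx, retro_track) {
  exonic_overlap_bp(tx, retro_track) >= 1L
}

#' Classify a pseudogene transcript as independent or dependent
#'
#' A transcript is independent iff (i) its exonic overlap with the
#' pseudogene strictly exceeds its exonic overlap with every
#' non-pseudogene gene model, and (ii) it is not intronic within any
#' non-pseudogene gene.
#'
#' @param tx A [transcript_model()] assigned to a pseudogene.
#' @param assigned The [pseudogene_record()] it was assigned to.
#' @param other_genes List of the remaining [gene_model()] objects.
#' @return `"independent"` or `"dependent"`.
#' @export
classify_independence <- function(tx, assigned, other_genes) {
  ov_pg <- exonic_overlap_bp(tx, gene_exon_set(assigned$gene))
  non_pg <- Filter(function(g)
    !g$biotype %in% c("processed_pseudogene", "unprocessed_pseudogene"),
    other_genes)
  for (g in non_pg) {
    if (exonic_overlap_bp(tx, gene_exon_set(g)) >= ov_pg)
      return("dependent")
    if (is_intronic(tx, g))
      return("dependent")
  }
  "independent"
}

#' Orientation of a pseudogene transcript relative to its parent gene
#'
#' A retrocopy's annotated strand encodes the parent-mRNA orientation, so
#' sense/antisense is decided against the pseudogene record's strand.
#'
#' @param tx A [transcript_model()].
#' @param pseudogene A [pseudogene_record()].
#' @return `"sense"` or `"antisense"`.
#' @export
classify_orientation <- function(tx, pseudogene) {
  ps <- pseudogene$retro_interval$strand
  if (ps == ".")
    stop("pseudogene strand is '.'; orientation undefined")
  if (tx$strand == ps) "sense" else "antisense"
}

tx_junctions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(character())
  sprintf("%s:%d-%d:%s", tx$chrom, tx$exons$end[-n], tx$exons$start[-1L],
          tx$strand)
}

#' Splice junctions shared with reference transcripts
#'
#' A junction is the (chrom, donor end, acceptor start, strand) tuple of a
#' consecutive exon pair; sharing requires exact coordinate identity.
#' Mono-exonic transcripts share nothing.
#'
#' @param tx A [transcript_model()].
#' @param reference_txs List of reference [transcript_model()] objects.
#' @return List with `shared` (logical) and `count` of matching junctions.
#' @export
shared_junctions <- function(tx, reference_txs) {
  j <- tx_junctions(tx)
  if (length(j) == 0L) return(list(shared = FALSE, count = 0L))
  ref <- unique(unlist(lapply(reference_txs, tx_junctions)))
  cnt <- sum(j %in% ref)
  list(shared = cnt >= 1L, count = cnt)
}

#' Classify a cohort of transcript models
#'
#' Runs the full per-transcript classification: read-support filtering,
#' best-overlap gene assignment, retrocopy confirmation, independence and
#' orientation calls, and reference junction sharing.
#'
#' @param txs List of [transcript_model()] objects.
#' @param genes Named list of [gene_model()] objects (the reference
#'   annotation, pseudogene gene models included).
#' @param pg_records Named list of [pseudogene_record()] objects keyed by
#'   pseudogene gene id.
#' @param retro_track An [interval_set()] of retrocopy intervals.
#' @param min_fl Minimum full-length read support (default 2).
#' @return data.frame with one row per retained transcript: `tx_id`,
#'   `assigned_gene_id`, `assignment_overlap_bp`, `assigned_biotype`,
#'   `is_pseudogene_transcript`, `retrocopy_confirmed`, `independence`,
#'   `orientation`, `multi_exonic`, `shares_reference_junction`,
#'   `shared_junction_count`, `fl_read_count`.
#' @export
classify_transcripts <- function(txs, genes, pg_records, retro_track,
                                 min_fl = 2L) {
  kept <- filter_by_support(txs, min_fl)
  ref_txs <- unlist(lapply(genes, function(g) g$transcripts), recursive = FALSE)
  ref_junc <- unique(unlist(lapply(ref_txs, tx_junctions)))
  # cache per-gene exon sets and spans; only genes whose span intersects
  # the transcript can win the assignment or affect independence
  gids <- vapply(genes, function(g) g$id, character(1))
  gsets <- lapply(genes, gene_exon_set)
  gspan <- lapply(genes, gene_span)
  span_chrom <- vapply(gspan, `[[`, character(1), "chrom")
  span_start <- vapply(gspan, `[[`, integer(1), "start")
  span_end <- vapply(gspan, `[[`, integer(1), "end")
  gbt <- vapply(genes, `[[`, character(1), "biotype")
  is_pg_bt <- gbt %in% c("processed_pseudogene", "unprocessed_pseudogene")
  rows <- lapply(kept, function(tx) {
    t0 <- min(tx$exons$start); t1 <- max(tx$exons$end)
    cand <- which(span_chrom == tx$chrom & span_start < t1 & span_end > t0)
    ov <- vapply(cand, function(i) exonic_overlap_bp(tx, gsets[[i]]),
                 integer(1))
    if (length(cand) == 0L || max(ov) == 0L) {
      asn <- list(gene_id = "none", overlap_bp = 0L)
    } else {
      best <- cand[ov == max(ov)]
      if (length(best) > 1L) {
        pgb <- is_pg_bt[best]
        if (any(pgb)) best <- best[pgb]
        best <- best[order(gids[best])]
      }
      asn <- list(gene_id = gids[best[1L]], overlap_bp = max(ov))
    }
    bt <- if (asn$gene_id == "none") NA_character_ else
      genes[[asn$gene_id]]$biotype
    is_pg_tx <- !is.na(bt) && bt == "processed_pseudogene"
    retro_ok <- confirm_retrocopy(tx, retro_track)
    indep <- NA_character_; orient <- NA_character_
    if (is_pg_tx && asn$gene_id %in% names(pg_records)) {
      rec <- pg_records[[asn$gene_id]]
      ov_pg <- asn$overlap_bp
      non_pg <- cand[!is_pg_bt[cand]]
      indep <- "independent"
      for (i in non_pg) {
        if (exonic_overlap_bp(tx, gsets[[i]]) >= ov_pg ||
            is_intronic(tx, genes[[i]])) {
          indep <- "dependent"
          break
        }
      }
      orient <- classify_orientation(tx, rec)
    }
    j <- tx_junctions(tx)
    sj <- list(shared = any(j %in% ref_junc), count = sum(j %in% ref_junc))
    data.frame(tx_id = tx$id, assigned_gene_id = asn$gene_id,
               assignment_overlap_bp = asn$overlap_bp,
               assigned_biotype = ifelse(is.na(bt), "none", bt),
               is_pseudogene_transcript = is_pg_tx,
               retrocopy_confirmed = retro_ok,
               independence = indep, orientation = orient,
               multi_exonic = nrow(tx$exons) > 1L,
               shares_reference_junction = sj$shared,
               shared_junction_count = sj$count,
               fl_read_count = tx$fl_read_count,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tx_id = character(), assigned_gene_id = character(),
               assignment_overlap_bp = integer(), assigned_biotype = character(),
               is_pseudogene_transcript = logical(), retrocopy_confirmed = logical(),
               independence = character(), orientation = character(),
               multi_exonic = logical(), shares_reference_junction = logical(),
               shared_junction_count = integer(), fl_read_count = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
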