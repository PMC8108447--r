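# Strand-blind interval algebra over 0-based half-open coordinates,
# backed by IRanges. Orientation is assessed separately by the classifier.

#' Normalised interval set
#'
#' Builds a sorted, merged (overlapping and book-ended intervals fused)
#' set of intervals, the unit of every intersection in the pipeline.
#' Merging is strand-blind.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Parallel 0-based half-open coordinates.
#' @return A data.frame with columns `chrom`, `start`, `end` and class
#'   `"interval_set"`.
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (length(chrom) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("intervals must satisfy 0 <= start < end")
  parts <- lapply(split(seq_along(chrom), chrom), function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1L, end = end[idx]),
                         min.gapwidth = 1L)
    data.frame(chrom = chrom[idx][1L],
               start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

set_on_chrom <- function(set, chrom) set[set$chrom == chrom, , drop = FALSE]

#' Overlap in base pairs between two intervals
#'
#' Length of the intersection `[max(starts), min(ends))`, clipped at zero.
#' Strand is ignored; intervals on different chromosomes overlap by 0.
#'
#' @param a,b [genomic_interval()] objects (or lists with `chrom`, `start`,
#'   `end`).
#' @return Non-negative integer.
#' @export
overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

#' Exonic overlap between a transcript and a feature set
#'
#' Sum over the transcript's exons of the overlap with the merged feature
#' set; each genomic base is counted at most once.
#'
#' @param tx A [transcript_model()].
#' @param feature An [interval_set()].
#' @return Non-negative integer number of overlapping bases.
#' @export
exonic_overlap_bp <- function(tx, feature) {
  f <- set_on_chrom(feature, tx$chrom)
  if (nrow(f) == 0L) return(0L)
  ex <- IRanges::IRanges(start = tx$exons$start + 1L, end = tx$exons$end)
  fr <- IRanges::IRanges(start = f$start + 1L, end = f$end)
  sum(IRanges::width(IRanges::intersect(ex, fr)))
}

#' Is a transcript intronic within a gene?
#'
#' TRUE iff the transcript's exon union has zero overlap with every exon of
#' the gene and the transcript lies entirely within the gene's genomic span.
#'
#' @param tx A [transcript_model()].
#' @param gene A [gene_model()] with at least one transcript.
#' @return Logical.
#' @export
is_intronic <- function(tx, gene) {
  span <- gene_span(gene)
  if (tx$chrom != span$chrom) return(FALSE)
  if (min(tx$exons$start) < span$start || max(tx$exons$end) > span$end)
    return(FALSE)
  exonic_overlap_bp(tx, gene_exon_set(gene)) == 0L
}

#' Distance from a point to the nearest interval
#'
#' Zero if the point falls inside an interval; otherwise the distance in
#' bases to the nearest covered base. Returns `Inf` when the set is empty
#' on that chromosome.
#'
#' @param chrom Chromosome of the point.
#' @param point 0-based position.
#' @param set An [interval_set()].
#' @return Non-negative number, possibly `Inf`.
#' @export
nearest_distance <- function(chrom, point, set) {
  s <- set_on_chrom(set, chrom)
  if (nrow(s) == 0L) return(Inf)
  inside <- any(point >= s$start & point < s$end)
  if (inside) return(0L)
  # distance to nearest covered base: s$start if left of interval, end-1 if right
  min(pmin(abs(s$start - point), abs(point - (s$end - 1L))))
}
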