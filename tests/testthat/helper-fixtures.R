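# Shared fixture builders and independent brute-force oracles. The
# oracles deliberately re-derive results from first principles (per-base
# membership, exhaustive enumeration) and never call the implementation
# paths they check.

mk_tx <- function(id, starts, ends, strand = "+", chrom = "chr1", fl = 2L) {
  transcript_model(id, chrom, strand, starts, ends, fl_read_count = fl)
}

mk_gene <- function(id, starts, ends, strand = "+", biotype = "protein_coding",
                    chrom = "chr1", cds = NULL) {
  tx <- mk_tx(paste0(id, ".t1"), starts, ends, strand, chrom)
  gene_model(id, biotype = biotype,
             transcripts = setNames(list(tx), tx$id), cds = cds)
}

# Per-base membership count of transcript exons inside a feature set.
bf_exonic_overlap <- function(tx, feature) {
  f <- feature[feature$chrom == tx$chrom, , drop = FALSE]
  covered <- unique(unlist(apply(f, 1L, function(r)
    seq.int(as.integer(r[["start"]]), as.integer(r[["end"]]) - 1L))))
  ex_bases <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq.int(tx$exons$start[i], tx$exons$end[i] - 1L)))
  sum(ex_bases %in% covered)
}

# Exhaustive enumeration of all ATG..stop spans; longest, 5'-most on tie.
bf_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (start in seq_len(max(0L, n - 5L))) {
    if (substring(s, start, start + 2L) != "ATG") next
    pos <- start + 3L
    while (pos + 2L <= n) {
      cod <- substring(s, pos, pos + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        aa_len <- (pos - start) / 3L
        if (is.null(best) || aa_len > best$aa_length)
          best <- list(start_nt = start - 1L, end_nt = pos + 2L,
                       aa_length = aa_len)
        break
      }
      pos <- pos + 3L
    }
  }
  best
}

# Exhaustive global alignment score with affine gaps (gap of length L
# costs open + L * ext), end gaps penalised.
bf_global_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "d"))
    if (i <= length(A))
      best <- max(best, -(if (prev == "u") ext else open + ext) +
                    rec(i + 1L, j, "u"))
    if (j <= length(B))
      best <- max(best, -(if (prev == "l") ext else open + ext) +
                    rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "start")
}

BF_STOPS <- c("TAA", "TAG", "TGA")

bf_aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# All orderings of differing positions, written as an iterative
# permutation sweep (independent of the recursive implementation).
bf_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  idx <- seq_along(v)
  if (length(v) == 2L) return(list(v, rev(v)))
  for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)))
    out[[length(out) + 1L]] <- v[p]
  out
}

# Brute-force NG86 pathway averaging for one codon pair.
bf_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a1 != a2)
  res <- list()
  for (ord in bf_perms(dpos)) {
    cur <- a1; sd <- 0; nd <- 0; stop_hit <- FALSE
    for (step in seq_along(ord)) {
      nxt <- cur; nxt[ord[step]] <- a2[ord[step]]
      cc <- paste(cur, collapse = ""); nc <- paste(nxt, collapse = "")
      if (bf_aa(cc) == bf_aa(nc)) sd <- sd + 1 else nd <- nd + 1
      if (step < length(ord) && nc %in% BF_STOPS) stop_hit <- TRUE
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(sd = sd, nd = nd, stop = as.numeric(stop_hit))
  }
  m <- do.call(rbind, res)
  keep <- m[m[, "stop"] == 0, , drop = FALSE]
  if (nrow(keep) == 0L) keep <- m
  c(sd = mean(keep[, "sd"]), nd = mean(keep[, "nd"]))
}

# Random sense-codon CDS (ATG-initiated, no internal stop).
random_sense_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE), BF_STOPS)
    paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                        collapse = ""))
  })
}

# Noise-free simulation settings shared by recovery tests.
recovery_config <- function(divergence = 0, indel_rate = 0, ...) {
  sim_config(n_parent_genes = 40L, n_pseudogenes = 50L,
             divergence = divergence, indel_rate = indel_rate,
             frameshift_fraction = 0, cage_jitter_sd = 0,
             fusion_count = 2L, intronic_insertion_fraction = 0.15,
             txs_per_pseudogene = c(3L, 4L), antisense_fraction = 0.2, ...)
}
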