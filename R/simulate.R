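# Synthetic genome and retrotransposition simulator. Generates parent
# genes, processed-pseudogene insertions with tunable divergence and
# frame disruption, sense/antisense/intronic/fusion transcripts with
# full-length read counts, CAGE peaks with jitter, planted genomic polyA
# motifs, per-pseudogene orthologous windows from a simulated second
# species, and a machine-readable truth manifest.

#' Simulation configuration
#'
#' Defaults describe a small mammalian-like cohort: multi-exon parent
#' genes with ~45% GC background, young processed pseudogenes at 1%
#' neutral divergence, a 20% antisense transcription rate, and an
#' ortholog branch at rhesus-like distance evolving under purifying
#' selection.
#'
#' @param n_parent_genes Number of parent protein-coding genes.
#' @param exons_per_gene Inclusive range `c(lo, hi)` of exons per gene.
#' @param cds_length_codons Range of parent ORF lengths (amino acids).
#' @param n_pseudogenes Number of processed pseudogene insertions.
#' @param divergence Per-base substitution probability on the pseudogene
#'   copy (human lineage, neutral).
#' @param indel_rate Per-base indel probability on the copy.
#' @param frameshift_fraction Fraction of (non-fusion) pseudogenes given
#'   a planted single-base frameshift.
#' @param antisense_fraction Probability an intergenic pseudogene
#'   transcript is antisense.
#' @param intronic_insertion_fraction Probability a pseudogene inserts
#'   into an intron of a coding gene.
#' @param fusion_count Number of gene-pseudogene fusion transcripts.
#' @param cage_jitter_sd Gaussian jitter (bases, sd) on CAGE peak centres.
#' @param fl_count_distribution List with `min` and geometric `prob` for
#'   full-length read counts (`min + rgeom(prob)`), so counts of `min`
#'   occur and exercise the support filter.
#' @param polya_motif_offset Range of planted polyA-motif offsets from
#'   the 3' terminus, within `[10, 40]`.
#' @param txs_per_pseudogene Range of transcript isoforms per intergenic
#'   pseudogene.
#' @param novel_exon_fraction Probability a sense isoform gains a novel
#'   5' exon from an upstream promoter.
#' @param utr5_length,utr3_length,intron_length,intergenic_gap Ranges
#'   (bases) for the corresponding parent-gene / layout elements; the 3'
#'   UTR minimum must stay >= 100 so the polyA scan window never reaches
#'   coding sequence.
#' @param fusion_codons Range of codons contributed by a fusion
#'   pseudogene.
#' @param n_background_peaks Number of background CAGE peaks.
#' @param cage_peak_width CAGE peak width (bases).
#' @param cage_depth Per-base CAGE signal depth over TSS peaks.
#' @param ortholog_t Proposed substitutions/site on the ortholog branch
#'   of pseudogene coding sequence.
#' @param ortholog_omega True dN/dS used on the ortholog branch.
#' @param ortholog_neutral_div Per-base substitution probability on
#'   ortholog non-coding sequence.
#' @param disable_reinitiation Build a fixture where downstream ORF
#'   re-initiation is impossible: parent CDS without internal Met codons,
#'   ATG scrubbed from UTRs, and planted frameshifts followed by an
#'   immediate in-frame stop.
#' @return List with class `"sim_config"`.
#' @export
sim_config <- function(n_parent_genes = 20L,
                       exons_per_gene = c(2L, 5L),
                       cds_length_codons = c(120L, 300L),
                       n_pseudogenes = 15L,
                       divergence = 0.01,
                       indel_rate = 5e-4,
                       frameshift_fraction = 0.3,
                       antisense_fraction = 0.2,
                       intronic_insertion_fraction = 0.15,
                       fusion_count = 1L,
                       cage_jitter_sd = 10,
                       fl_count_distribution = list(min = 1L, prob = 0.35),
                       polya_motif_offset = c(10L, 40L),
                       txs_per_pseudogene = c(1L, 3L),
                       novel_exon_fraction = 0.5,
                       utr5_length = c(60L, 150L),
                       utr3_length = c(100L, 200L),
                       intron_length = c(200L, 600L),
                       intergenic_gap = c(2000L, 4000L),
                       fusion_codons = c(30L, 100L),
                       n_background_peaks = 20L,
                       cage_peak_width = 20L,
                       cage_depth = 5,
                       ortholog_t = 0.08,
                       ortholog_omega = 0.4,
                       ortholog_neutral_div = 0.08,
                       disable_reinitiation = FALSE) {
  cfg <- as.list(environment())
  fr <- c("divergence", "indel_rate", "frameshift_fraction",
          "antisense_fraction", "intronic_insertion_fraction",
          "novel_exon_fraction", "ortholog_omega", "ortholog_neutral_div")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must lie in [0, 1]")
  rng <- c("exons_per_gene", "cds_length_codons", "polya_motif_offset",
           "txs_per_pseudogene", "utr5_length", "utr3_length",
           "intron_length", "intergenic_gap", "fusion_codons")
  for (f in rng) {
    r <- cfg[[f]]
    if (length(r) == 1L) r <- c(r, r)
    if (r[2] < r[1]) stop(f, " range is empty")
    cfg[[f]] <- as.integer(r)
  }
  if (cfg$polya_motif_offset[1] < 10L || cfg$polya_motif_offset[2] > 40L)
    stop("polya_motif_offset must lie within [10, 40]")
  if (cfg$utr3_length[1] < 100L)
    stop("utr3_length minimum must be >= 100")
  if (cfg$fusion_count > cfg$n_pseudogenes)
    stop("fusion_count cannot exceed n_pseudogenes")
  structure(cfg, class = "sim_config")
}

# --- internal sequence machinery ------------------------------------------

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

# Substitutions + indels with a coordinate map old position -> new (NA if
# deleted). Insertions add one random base before the event position.
mutate_seq <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  map <- seq_len(n) - 1L
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    if (length(ev)) {
      kind <- sample(c("del", "ins"), length(ev), replace = TRUE)
      del <- ev[kind == "del"]; ins <- ev[kind == "ins"]
      keep <- rep(TRUE, n); keep[del] <- FALSE
      ins_flag <- integer(n); ins_flag[ins] <- 1L
      kept_cum <- cumsum(keep); ins_cum <- cumsum(ins_flag)
      map <- ifelse(keep, kept_cum - 1L + ins_cum, NA_integer_)
      new_chars <- character(n - length(del) + length(ins))
      new_chars[map[keep] + 1L] <- chars[keep]
      if (length(ins)) {
        idx <- kept_cum[ins] - as.integer(keep[ins]) + ins_cum[ins] - 1L
        new_chars[idx + 1L] <- sample(BASES, length(ins), replace = TRUE)
      }
      chars <- new_chars
    }
  }
  list(seq = paste(chars, collapse = ""), map = map)
}

# Remove every ATG except the one starting at 0-based position keep_at.
scrub_atg <- function(seq, keep_at = NA_integer_) {
  repeat {
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    hits0 <- hits - 1L
    bad <- hits0[is.na(keep_at) | hits0 != keep_at]
    if (!length(bad)) break
    substr(seq, bad[1] + 3L, bad[1] + 3L) <- "C"  # G -> C never creates ATG
  }
  seq
}

random_cds <- function(aa_len, no_internal_met = FALSE) {
  pool <- if (no_internal_met) setdiff(SENSE_CODONS, "ATG") else SENSE_CODONS
  body <- sample(pool, aa_len - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# Map an interval in sense-body coordinates [q1, q2) to local genomic
# coordinates, given the body occupies [off, off + len) and sits on
# `strand` of the locus.
body_to_local <- function(q1, q2, strand, off, len) {
  if (strand == "+") c(off + q1, off + q2) else c(off + len - q2, off + len - q1)
}

#' Generate a synthetic multi-exon parent gene
#'
#' Builds an mRNA (5' UTR, ATG...stop CDS of the configured codon length,
#' 3' UTR), splits it into exons, inserts introns with GT..AG ends, and
#' lays the locus out on a randomly chosen strand. Deterministic under
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param id Gene identifier.
#' @param force_strand Optional strand override.
#' @return List describing the gene locus in local coordinates: `seq`,
#'   `strand`, `exons` (data.frame), `cds` (data.frame), `mrna`,
#'   `aa_length`, `utr5_len`, `utr3_len`.
#' @export
make_parent_gene <- function(config, seed, id = "G001", force_strand = NULL) {
  with_seed(seed, build_parent_gene(config, id, force_strand))
}

build_parent_gene <- function(config, id, force_strand = NULL) {
  aa <- sample_range(config$cds_length_codons)
  cds <- random_cds(aa, no_internal_met = config$disable_reinitiation)
  utr5 <- random_dna(sample_range(config$utr5_length))
  utr3 <- random_dna(sample_range(config$utr3_length))
  mrna <- paste0(utr5, cds, utr3)
  if (config$disable_reinitiation)
    mrna <- scrub_atg(mrna, keep_at = nchar(utr5))
  m <- nchar(mrna)
  k <- sample_range(config$exons_per_gene)
  cuts <- integer(0)
  if (k > 1L) {
    repeat {
      cuts <- sort(sample(seq(30L, m - 30L), k - 1L))
      if (all(diff(c(0L, cuts, m)) >= 30L)) break
    }
  }
  bounds <- c(0L, cuts, m)  # mRNA spans of the k exon pieces
  introns <- if (k > 1L) vapply(seq_len(k - 1L), function(i) {
    len <- sample_range(config$intron_length)
    paste0("GT", random_dna(len - 4L), "AG")
  }, character(1)) else character(0)
  # sense-orientation layout
  pieces <- substring(mrna, bounds[-length(bounds)] + 1L, bounds[-1L])
  seq_plus <- pieces[1L]
  ex_start <- integer(k); ex_end <- integer(k)
  ex_start[1L] <- 0L; ex_end[1L] <- nchar(pieces[1L])
  if (k > 1L) for (i in 2:k) {
    seq_plus <- paste0(seq_plus, introns[i - 1L], pieces[i])
    ex_start[i] <- ex_end[i - 1L] + nchar(introns[i - 1L])
    ex_end[i] <- ex_start[i] + nchar(pieces[i])
  }
  # CDS mRNA span -> local (sense) intervals
  cds_m <- c(nchar(utr5), nchar(utr5) + nchar(cds))
  cds_iv <- list()
  for (i in seq_len(k)) {
    a <- max(bounds[i], cds_m[1]); b <- min(bounds[i + 1L], cds_m[2])
    if (b > a)
      cds_iv[[length(cds_iv) + 1L]] <-
        c(ex_start[i] + (a - bounds[i]), ex_start[i] + (b - bounds[i]))
  }
  cds_df <- data.frame(start = vapply(cds_iv, `[`, numeric(1), 1L),
                       end = vapply(cds_iv, `[`, numeric(1), 2L))
  strand <- if (!is.null(force_strand)) force_strand else sample(c("+", "-"), 1L)
  L <- nchar(seq_plus)
  if (strand == "-") {
    seq_loc <- revcomp(seq_plus)
    flip <- function(df) {
      out <- data.frame(start = L - df$end, end = L - df$start)
      out[order(out$start), , drop = FALSE]
    }
    exons <- flip(data.frame(start = ex_start, end = ex_end))
    cds_df <- flip(cds_df)
  } else {
    seq_loc <- seq_plus
    exons <- data.frame(start = ex_start, end = ex_end)
  }
  rownames(exons) <- rownames(cds_df) <- NULL
  list(id = id, seq = seq_loc, strand = strand, exons = exons, cds = cds_df,
       mrna = mrna, aa_length = aa, utr5_len = nchar(utr5),
       utr3_len = nchar(utr3))
}

# Retrotranspose a parent mRNA: copy, append a polyA tract, apply
# divergence/indels, optionally plant a frameshift at a recorded CDS
# fraction. Returns the diverged body (sense orientation), the ancestral
# body, the CDS location in new coordinates, and bookkeeping.
retropose_mrna <- function(parent, config, frameshift, hard = FALSE,
                           allow_indels = TRUE) {
  tract <- strrep("A", sample_range(c(8L, 20L)))
  anc <- parent$mrna
  mut <- mutate_seq(anc, config$divergence,
                    if (allow_indels) config$indel_rate else 0)
  body <- mut$seq; map <- mut$map
  map_pos <- function(p) {  # nearest retained new coordinate at/after p
    q <- map[(p + 1L):length(map)]
    q <- q[!is.na(q)]
    if (!length(q)) NA_integer_ else q[1L]
  }
  cds_start_new <- map_pos(parent$utr5_len)
  fs_fraction <- NA_real_
  if (frameshift) {
    fs_fraction <- runif(1L, 0.2, 0.8)
    kcod <- as.integer(floor(fs_fraction * parent$aa_length))
    kcod <- max(1L, min(parent$aa_length - 2L, kcod))
    p_anc <- parent$utr5_len + 3L * kcod
    p <- map_pos(p_anc)
    if (!is.na(p) && p + 4L <= nchar(body)) {
      # delete one base, then force an immediate in-frame stop when the
      # no-reinitiation fixture is active
      body <- paste0(substring(body, 1L, p), substring(body, p + 2L, nchar(body)))
      if (hard)
        body <- paste0(substring(body, 1L, p),
                       "TAA", substring(body, p + 4L, nchar(body)))
    }
  }
  list(body = paste0(body, tract), anc_body = paste0(anc, tract),
       cds_start_new = cds_start_new, cds_len = 3L * (parent$aa_length + 1L),
       frameshift = frameshift, frameshift_fraction = fs_fraction,
       tract_len = nchar(tract))
}

# Orthologous window for a pseudogene: the ancestral insertion re-diverged
# along a second-species branch (neutral on UTRs/flanks, codon model with
# true omega on the CDS), padded with unrelated flanks.
ortholog_window <- function(parent, config) {
  neutral <- function(s) {
    if (!nzchar(s)) return(s)
    mutate_seq(s, config$ortholog_neutral_div, 0)$seq
  }
  utr5 <- substring(parent$mrna, 1L, parent$utr5_len)
  cds_all <- substring(parent$mrna, parent$utr5_len + 1L,
                       parent$utr5_len + 3L * (parent$aa_length + 1L))
  cds_nostop <- substring(cds_all, 1L, nchar(cds_all) - 3L)
  stopc <- substring(cds_all, nchar(cds_all) - 2L, nchar(cds_all))
  utr3 <- substring(parent$mrna, parent$utr5_len + nchar(cds_all) + 1L,
                    nchar(parent$mrna))
  sub_seed <- sample.int(.Machine$integer.max, 1L)
  cds_div <- simulate_codon_divergence(cds_nostop, config$ortholog_t,
                                       config$ortholog_omega, sub_seed)
  paste0(random_dna(250L), neutral(utr5), cds_div, stopc, neutral(utr3),
         random_dna(250L))
}

# Overwrite the polyA-scan window at a transcript 3' end with a planted
# motif at `offset`, and scrub any other motif occurrence in the window.
plant_polya <- function(chrom_seq, tx_start, tx_end, strand, motif, offset,
                        window = 100L) {
  if (strand == "+") {
    a <- tx_end - window; b <- tx_end
    win <- substring(chrom_seq, a + 1L, b)
  } else {
    a <- tx_start; b <- tx_start + window
    win <- revcomp(substring(chrom_seq, a + 1L, b))
  }
  w <- nchar(win)
  ps <- w - offset - 6L  # 0-based motif start in oriented window
  substr(win, ps + 1L, ps + 6L) <- motif
  repeat {
    occ_start <- integer(0); occ_motif <- character(0)
    for (m in POLYA_MOTIFS) {
      h <- gregexpr(m, win, fixed = TRUE)[[1]]
      if (h[1] != -1L) {
        occ_start <- c(occ_start, h - 1L)
        occ_motif <- c(occ_motif, rep(m, length(h)))
      }
    }
    bad <- which(!(occ_start == ps & occ_motif == motif))
    if (!length(bad)) break
    b0 <- occ_start[bad[1L]]
    cand <- setdiff(seq(b0, b0 + 5L), seq(ps, ps + 5L))
    substr(win, cand[1L] + 1L, cand[1L] + 1L) <- "C"
  }
  if (strand == "+") {
    paste0(substring(chrom_seq, 1L, a), win,
           substring(chrom_seq, b + 1L, nchar(chrom_seq)))
  } else {
    paste0(substring(chrom_seq, 1L, a), revcomp(win),
           substring(chrom_seq, b + 1L, nchar(chrom_seq)))
  }
}

# --- orchestrator ----------------------------------------------------------

#' Simulate a pseudogene transcriptome cohort
#'
#' Builds a single synthetic chromosome carrying parent genes and
#' processed-pseudogene insertions, plants sense / antisense / intronic /
#' fusion transcripts with read counts, polyA motifs and CAGE peaks, and
#' records every planted label in a truth manifest. A pure function of
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with class `"pseudogene_sim"`: `genome` (named character),
#'   `genes`, `pg_records`, `retro_track` ([interval_set()]),
#'   `retro_bed` (data.frame), `transcripts` (named list),
#'   `cage_peaks`, `cage_signal` (data.frames), `ortholog_windows`
#'   (named character), `truth` (list of data.frames `transcripts`,
#'   `pseudogenes`), `config`, `seed`.
#' @export
simulate_pseudogene_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_seed(seed, build_cohort(config))
  out$seed <- as.integer(seed)
  out
}

build_cohort <- function(config) {
  n_par <- config$n_parent_genes
  n_pg <- config$n_pseudogenes
  if (n_par < 1L) stop("need at least one parent gene")
  n_fusion <- min(config$fusion_count, n_pg)
  parents <- vector("list", n_par)
  for (i in seq_len(n_par)) {
    gid <- sprintf("G%03d", i)
    # fusion hosts are forced to '+' so the fused ORF reads left to right
    force <- if (n_fusion > 0L && i <= n_fusion) "+" else NULL
    parents[[i]] <- build_parent_gene(config, gid, force_strand = force)
  }
  names(parents) <- vapply(parents, `[[`, character(1), "id")

  # --- plan pseudogenes ---
  pgs <- vector("list", n_pg)
  fusion_ids <- if (n_fusion > 0L) seq(n_pg - n_fusion + 1L, n_pg) else integer(0)
  used_hosts <- integer(0)  # one intronic insertion per host gene
  for (j in seq_len(n_pg)) {
    pid <- sprintf("PSG%03d", j)
    is_fusion <- j %in% fusion_ids
    parent_idx <- if (is_fusion) {
      # parent must differ from the designated host (host index = rank of
      # the fusion among fusion slots)
      host <- match(j, fusion_ids)
      ((host) %% n_par) + 1L
    } else ((j - 1L) %% n_par) + 1L
    parent <- parents[[parent_idx]]
    frameshift <- !is_fusion && runif(1L) < config$frameshift_fraction
    rp <- retropose_mrna(parent, config, frameshift,
                         hard = config$disable_reinitiation,
                         allow_indels = !is_fusion)
    strand <- if (is_fusion) "+" else sample(c("+", "-"), 1L)
    intronic <- !is_fusion && runif(1L) < config$intronic_insertion_fraction
    host_idx <- NA_integer_
    if (intronic) {
      ok <- which(vapply(parents, function(p) nrow(p$exons) >= 2L, logical(1)))
      ok <- setdiff(ok, seq_len(n_fusion))  # keep fusion hosts untouched
      ok <- setdiff(ok, parent_idx)
      ok <- setdiff(ok, used_hosts)
      if (!length(ok)) intronic <- FALSE else {
        host_idx <- if (length(ok) == 1L) ok else sample(ok, 1L)
        used_hosts <- c(used_hosts, host_idx)
      }
    }
    pgs[[j]] <- list(id = pid, parent = parent$id, parent_idx = parent_idx,
                     rp = rp, strand = strand, intronic = intronic,
                     host_idx = host_idx, is_fusion = is_fusion,
                     fusion_host = if (is_fusion)
                       parents[[match(j, fusion_ids)]]$id else NA_character_)
  }

  # --- insert intronic pseudogenes into host loci ---
  pg_local <- vector("list", n_pg)  # local retro body interval + locus ref
  for (j in seq_len(n_pg)) {
    pg <- pgs[[j]]
    if (!isTRUE(pg$intronic)) next
    host <- parents[[pg$host_idx]]
    body <- if (pg$strand == "+") pg$rp$body else revcomp(pg$rp$body)
    ins_seq <- paste0(random_dna(50L), body, random_dna(50L))
    # middle of a random intron (local genomic coords)
    k <- nrow(host$exons)
    gaps <- data.frame(start = host$exons$end[-k], end = host$exons$start[-1L])
    gi <- sample.int(nrow(gaps), 1L)
    p <- as.integer((gaps$start[gi] + gaps$end[gi]) / 2)
    host$seq <- paste0(substring(host$seq, 1L, p), ins_seq,
                       substring(host$seq, p + 1L, nchar(host$seq)))
    shift <- nchar(ins_seq)
    host$exons$start <- host$exons$start + ifelse(host$exons$start >= p, shift, 0L)
    host$exons$end <- host$exons$end + ifelse(host$exons$end > p, shift, 0L)
    host$cds$start <- host$cds$start + ifelse(host$cds$start >= p, shift, 0L)
    host$cds$end <- host$cds$end + ifelse(host$cds$end > p, shift, 0L)
    parents[[pg$host_idx]] <- host
    pg_local[[j]] <- list(type = "intronic", locus = pg$host_idx,
                          body_start = p + 50L,
                          body_end = p + 50L + nchar(body))
  }

  # --- build intergenic pseudogene loci ---
  promoter_pad <- 400L; tail_pad <- 200L
  pg_locus <- vector("list", n_pg)
  for (j in seq_len(n_pg)) {
    pg <- pgs[[j]]
    if (isTRUE(pg$intronic)) next
    body_sense <- pg$rp$body
    Lb <- nchar(body_sense)
    body <- if (pg$strand == "+") body_sense else revcomp(body_sense)
    left <- if (pg$strand == "+") promoter_pad else tail_pad
    right <- if (pg$strand == "+") tail_pad else promoter_pad
    pg_locus[[j]] <- list(seq = paste0(random_dna(left), body, random_dna(right)),
                          body_start = left, body_end = left + Lb,
                          body_len = Lb)
    pg_local[[j]] <- list(type = "intergenic", locus = NA_integer_)
  }

  # --- chromosome layout ---
  chrom <- "chr1"
  chunks <- character(0)
  offset <- 0L
  gene_off <- integer(n_par)     # locus offset per parent gene
  pg_off <- rep(NA_integer_, n_pg)
  add_chunk <- function(s) {
    chunks[[length(chunks) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  add_gap <- function() add_chunk(random_dna(sample_range(config$intergenic_gap)))
  add_gap()
  for (i in seq_len(n_par)) {
    # a fusion pseudogene sits immediately upstream of its (+) host
    fj <- which(vapply(pgs, function(p)
      p$is_fusion && p$fusion_host == parents[[i]]$id, logical(1)))
    if (length(fj) == 1L) {
      pg_off[fj] <- offset
      add_chunk(pg_locus[[fj]]$seq)
      add_chunk(random_dna(150L))
    }
    gene_off[i] <- offset
    add_chunk(parents[[i]]$seq)
    add_gap()
  }
  for (j in seq_len(n_pg)) {
    if (pgs[[j]]$intronic || pgs[[j]]$is_fusion) next
    pg_off[j] <- offset
    add_chunk(pg_locus[[j]]$seq)
    add_gap()
  }
  genome_seq <- paste(chunks, collapse = "")

  # --- global annotation ---
  genes <- list()
  for (i in seq_len(n_par)) {
    p <- parents[[i]]
    off <- gene_off[i]
    tx <- transcript_model(id = paste0(p$id, ".t1"), chrom = chrom,
                           strand = p$strand,
                           exon_starts = p$exons$start + off,
                           exon_ends = p$exons$end + off)
    genes[[p$id]] <- gene_model(id = p$id, name = p$id,
                                biotype = "protein_coding",
                                transcripts = setNames(list(tx), tx$id),
                                cds = data.frame(start = p$cds$start + off,
                                                 end = p$cds$end + off))
  }
  pg_records <- list()
  retro_rows <- list()
  pg_global <- vector("list", n_pg)  # global body interval per pseudogene
  for (j in seq_len(n_pg)) {
    pg <- pgs[[j]]
    if (pg$intronic) {
      off <- gene_off[[pg_local[[j]]$locus]]
      # the insertion shifted the host locus; body coords were recorded in
      # post-insertion host-local coordinates
      b0 <- pg_local[[j]]$body_start + off
      b1 <- pg_local[[j]]$body_end + off
    } else {
      b0 <- pg_locus[[j]]$body_start + pg_off[j]
      b1 <- pg_locus[[j]]$body_end + pg_off[j]
    }
    pg_global[[j]] <- c(b0, b1)
    ptx <- transcript_model(id = paste0(pg$id, ".t1"), chrom = chrom,
                            strand = pg$strand, exon_starts = b0,
                            exon_ends = b1)
    pgene <- gene_model(id = pg$id, name = paste0(pgs[[j]]$parent, "P"),
                        biotype = "processed_pseudogene",
                        transcripts = setNames(list(ptx), ptx$id))
    genes[[pg$id]] <- pgene
    pg_records[[pg$id]] <- pseudogene_record(
      pgene, parent_gene_id = pg$parent,
      retro_interval = genomic_interval(chrom, b0, b1, pg$strand))
    retro_rows[[j]] <- data.frame(chrom = chrom, start = b0, end = b1,
                                  name = pg$id, score = 0L,
                                  strand = pg$strand,
                                  stringsAsFactors = FALSE)
  }
  retro_bed <- if (n_pg > 0L) do.call(rbind, retro_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character(),
               stringsAsFactors = FALSE)
  retro_track <- if (n_pg > 0L)
    interval_set(retro_bed$chrom, retro_bed$start, retro_bed$end)
  else interval_set()

  # --- plant expressed transcripts ---
  txs <- list()
  truth_rows <- list()
  draw_fl <- function() config$fl_count_distribution$min +
    rgeom(1L, config$fl_count_distribution$prob)
  add_tx <- function(tx, label, pg_id = NA_character_,
                     parent_id = NA_character_, codons = NA_integer_) {
    txs[[tx$id]] <<- tx
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      tx_id = tx$id, label = label, tss = transcript_tss(tx),
      strand = tx$strand, fl_read_count = tx$fl_read_count,
      pseudogene_id = pg_id, parent_gene_id = parent_id,
      codons_from_pseudogene = codons,
      polya_motif = NA_character_, polya_offset = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_par)) {
    p <- parents[[i]]
    atx <- genes[[p$id]]$transcripts[[1L]]
    tx <- transcript_model(id = paste0(p$id, ".iso1"), chrom = chrom,
                           strand = p$strand,
                           exon_starts = atx$exons$start,
                           exon_ends = atx$exons$end,
                           fl_read_count = draw_fl())
    add_tx(tx, "parent_mRNA", parent_id = p$id)
  }
  for (j in seq_len(n_pg)) {
    pg <- pgs[[j]]
    b <- pg_global[[j]]; b0 <- b[1]; b1 <- b[2]
    Lb <- b1 - b0
    if (pg$is_fusion) {
      host <- parents[[match(pg$fusion_host, names(parents))]]
      hoff <- gene_off[match(pg$fusion_host, names(parents))]
      m <- sample_range(config$fusion_codons)
      m <- min(m, host$aa_length - 20L)
      # first m codons of the copied CDS, in body-sense coordinates
      cs <- pg$rp$cds_start_new
      e1 <- body_to_local(cs, cs + 3L * m, pg$strand, b0, Lb)
      cds_start_g <- min(host$cds$start) + hoff
      hex <- data.frame(start = host$exons$start + hoff,
                        end = host$exons$end + hoff)
      hex <- hex[hex$end > cds_start_g, , drop = FALSE]
      hex$start[1L] <- max(hex$start[1L], cds_start_g)
      tx <- transcript_model(id = paste0(pg$id, ".fusion1"), chrom = chrom,
                             strand = "+",
                             exon_starts = c(e1[1], hex$start),
                             exon_ends = c(e1[2], hex$end),
                             fl_read_count = draw_fl())
      add_tx(tx, "fusion", pg_id = pg$id, parent_id = pg$fusion_host,
             codons = m)
      next
    }
    if (pg$intronic) {
      tx <- transcript_model(id = paste0(pg$id, ".iso1"), chrom = chrom,
                             strand = pg$strand, exon_starts = b0,
                             exon_ends = b1, fl_read_count = draw_fl())
      add_tx(tx, "dependent_intronic", pg_id = pg$id, parent_id = pg$parent)
      next
    }
    n_iso <- sample_range(config$txs_per_pseudogene)
    # one shared antisense 3' end per pseudogene, so planted polyA-motif
    # windows of antisense isoforms never overlap each other
    e <- sample_range(c(60L, 100L))
    for (iso in seq_len(n_iso)) {
      anti <- runif(1L) < config$antisense_fraction
      if (anti) {
        # runs opposite to the retrocopy; its 3' end pokes into the
        # promoter pad so the polyA window never reaches the copied CDS
        d <- sample_range(c(0L, 20L))
        iv <- body_to_local(-e, Lb - d, pg$strand, b0, Lb)
        tx <- transcript_model(
          id = sprintf("%s.iso%d", pg$id, iso), chrom = chrom,
          strand = if (pg$strand == "+") "-" else "+",
          exon_starts = iv[1], exon_ends = iv[2],
          fl_read_count = draw_fl())
        add_tx(tx, "independent_antisense", pg_id = pg$id,
               parent_id = pg$parent)
      } else {
        delta <- if (iso == 1L) 0L else sample_range(c(5L, 30L))
        novel <- runif(1L) < config$novel_exon_fraction
        iv_body <- body_to_local(delta, Lb, pg$strand, b0, Lb)
        if (novel) {
          gap <- sample_range(c(80L, 150L))
          iv_nov <- body_to_local(-(gap + 80L), -gap, pg$strand, b0, Lb)
          starts <- sort(c(iv_nov[1], iv_body[1]))
          ends <- sort(c(iv_nov[2], iv_body[2]))
        } else {
          starts <- iv_body[1]; ends <- iv_body[2]
        }
        tx <- transcript_model(id = sprintf("%s.iso%d", pg$id, iso),
                               chrom = chrom, strand = pg$strand,
                               exon_starts = starts, exon_ends = ends,
                               fl_read_count = draw_fl())
        add_tx(tx, "independent_sense", pg_id = pg$id, parent_id = pg$parent)
      }
    }
  }
  truth_tx <- do.call(rbind, truth_rows)

  # --- plant polyA motifs (one planting per distinct 3' end) ---
  ends3 <- vapply(txs, function(tx) {
    if (tx$strand == "+") sprintf("+:%d", max(tx$exons$end))
    else sprintf("-:%d", min(tx$exons$start))
  }, character(1))
  planted <- new.env(parent = emptyenv())
  for (k in seq_along(txs)) {
    key <- ends3[k]
    if (is.null(planted[[key]])) {
      motif <- sample(POLYA_MOTIFS, 1L, prob = c(2, 1))
      off <- sample_range(config$polya_motif_offset)
      tx <- txs[[k]]
      genome_seq <- plant_polya(genome_seq, min(tx$exons$start),
                                max(tx$exons$end), tx$strand, motif, off)
      planted[[key]] <- list(motif = motif, offset = off)
    }
    truth_tx$polya_motif[k] <- planted[[key]]$motif
    truth_tx$polya_offset[k] <- planted[[key]]$offset
  }

  # --- CAGE peaks and signal ---
  half <- as.integer(config$cage_peak_width / 2)
  peak_rows <- lapply(seq_along(txs), function(k) {
    tss <- truth_tx$tss[k]
    center <- tss + as.integer(round(rnorm(1L, 0, config$cage_jitter_sd)))
    data.frame(chrom = chrom, start = max(0L, center - half),
               end = center + half, name = paste0("peak_", truth_tx$tx_id[k]),
               score = config$cage_depth, strand = ".",
               stringsAsFactors = FALSE)
  })
  glen <- nchar(genome_seq)
  bg_rows <- lapply(seq_len(config$n_background_peaks), function(k) {
    c0 <- sample.int(glen - config$cage_peak_width, 1L)
    data.frame(chrom = chrom, start = c0, end = c0 + config$cage_peak_width,
               name = sprintf("bg_%03d", k), score = 1, strand = ".",
               stringsAsFactors = FALSE)
  })
  cage_peaks <- do.call(rbind, c(peak_rows, bg_rows))
  cage_signal <- cage_peaks[, c("chrom", "start", "end", "score")]

  # --- ortholog windows ---
  orth <- vapply(seq_len(n_pg), function(j)
    ortholog_window(parents[[pgs[[j]]$parent_idx]], config), character(1))
  names(orth) <- vapply(pgs, `[[`, character(1), "id")

  truth_pg <- if (n_pg > 0L) do.call(rbind, lapply(seq_len(n_pg), function(j) {
    pg <- pgs[[j]]
    data.frame(pseudogene_id = pg$id, parent_gene_id = pg$parent,
               start = pg_global[[j]][1], end = pg_global[[j]][2],
               strand = pg$strand,
               intronic = isTRUE(pg$intronic),
               host_gene_id = if (pg$intronic) parents[[pg$host_idx]]$id
               else NA_character_,
               is_fusion = pg$is_fusion,
               frameshift = pg$rp$frameshift,
               frameshift_fraction = pg$rp$frameshift_fraction,
               divergence = config$divergence,
               parent_orf_aa = parents[[pg$parent_idx]]$aa_length,
               stringsAsFactors = FALSE)
  })) else data.frame()

  structure(list(
    genome = setNames(genome_seq, chrom)[chrom],
    genes = genes, pg_records = pg_records,
    retro_track = retro_track, retro_bed = retro_bed,
    transcripts = txs, cage_peaks = cage_peaks, cage_signal = cage_signal,
    ortholog_windows = orth,
    truth = list(transcripts = truth_tx, pseudogenes = truth_pg),
    config = config, seed = NA_integer_), class = "pseudogene_sim")
}

#' @export
print.pseudogene_sim <- function(x, ...) {
  cat(sprintf(
    "<pseudogene_sim> %d bp genome, %d genes (%d pseudogenes), %d transcripts\n",
    nchar(x$genome[[1]]), length(x$genes), length(x$pg_records),
    length(x$transcripts)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits genome FASTA, annotation GTF, retrocopy BED6, transcript BED12
#' plus abundance TSV, CAGE peak BED and signal bedGraph, ortholog-window
#' FASTA, parent-linkage TSV and the truth manifest (TSV + JSON). All
#' outputs re-parse losslessly through the package readers.
#'
#' @param sim A `"pseudogene_sim"` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(sim$genes, file.path(outdir, "annotation.gtf"))
  write_bed6(sim$retro_bed, file.path(outdir, "retro.bed"))
  write_bed12(sim$transcripts, file.path(outdir, "transcripts.bed"))
  ab <- data.frame(tx_id = names(sim$transcripts),
                   fl_read_count = vapply(sim$transcripts, `[[`, integer(1),
                                          "fl_read_count"))
  write_tsv_report(ab, file.path(outdir, "abundance.tsv"))
  write_bed6(sim$cage_peaks, file.path(outdir, "cage_peaks.bed"))
  write_bedgraph(sim$cage_signal, file.path(outdir, "cage_signal.bedGraph"))
  if (length(sim$ortholog_windows))
    write_fasta(sim$ortholog_windows, file.path(outdir, "ortholog_windows.fa"))
  links <- data.frame(pseudogene_id = names(sim$pg_records),
                      parent_gene_id = vapply(sim$pg_records, `[[`,
                                              character(1), "parent_gene_id"))
  write_tsv_report(links, file.path(outdir, "parents.tsv"))
  write_tsv_report(sim$truth$transcripts,
                   file.path(outdir, "truth_transcripts.tsv"))
  write_tsv_report(sim$truth$pseudogenes,
                   file.path(outdir, "truth_pseudogenes.tsv"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
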