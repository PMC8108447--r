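# End-to-end orchestration: classify a cohort, score features, analyse
# ORFs and fusions, estimate selection, and summarise.

#' Analyse a pseudogene transcript cohort
#'
#' Chains the full pipeline over in-memory inputs (a
#' `"pseudogene_sim"` object, or any list with the same elements built
#' from files via [load_simulation()]): support filtering and
#' classification, TSS/CAGE and polyA features, ORF and parental-ORF
#' fraction analysis, fusion detection, and pairwise dN/dS against
#' per-pseudogene orthologous windows.
#'
#' @param cohort List with elements `genome`, `genes`, `pg_records`,
#'   `retro_track`, `transcripts`, `cage_peaks`, `cage_signal`
#'   (optional), `ortholog_windows` (optional).
#' @param min_fl Minimum full-length read support (default 2).
#' @param cage_window CAGE support window in bases (default 100).
#' @param polya_window PolyA scan window in bases (default 100).
#' @return List with `classified`, `features`, `orfs`, `fusions`,
#'   `dnds_table`, `dnds_estimates`, `dnds_summary`, `labels`, `summary`.
#' @export
analyze_cohort <- function(cohort, min_fl = 2L, cage_window = 100L,
                           polya_window = 100L) {
  txs <- cohort$transcripts
  classified <- classify_transcripts(txs, cohort$genes, cohort$pg_records,
                                     cohort$retro_track, min_fl = min_fl)
  kept <- txs[classified$tx_id]
  peaks <- interval_set(cohort$cage_peaks$chrom, cohort$cage_peaks$start,
                        cohort$cage_peaks$end)
  feat_rows <- lapply(kept, function(tx) {
    tss <- transcript_tss(tx)
    cs <- cage_support(tx$chrom, tss, peaks, window = cage_window)
    pa <- polya_scan(tx, cohort$genome, window = polya_window)
    data.frame(tx_id = tx$id, tss = tss,
               cage_distance = cs$distance_to_peak,
               cage_supported = cs$supported,
               polya_motif = pa$motif,
               polya_offset = if (is.na(pa$offset_from_3prime)) NA_integer_
               else pa$offset_from_3prime,
               stringsAsFactors = FALSE)
  })
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    data.frame(tx_id = character(), tss = integer(), cage_distance = numeric(),
               cage_supported = logical(), polya_motif = character(),
               polya_offset = integer())
  rownames(features) <- NULL

  # ORFs for pseudogene-assigned transcripts, with parental ORF fraction
  orf_rows <- lapply(seq_len(nrow(classified)), function(i) {
    row <- classified[i, ]
    if (!row$is_pseudogene_transcript) return(NULL)
    tx <- txs[[row$tx_id]]
    orf <- find_longest_orf(tx_spliced_seq(tx, cohort$genome))
    rec <- cohort$pg_records[[row$assigned_gene_id]]
    par <- cohort$genes[[rec$parent_gene_id]]
    pfrac <- if (!is.null(par) && !is.null(par$cds))
      parent_orf_fraction(orf, parent_orf_length(par)) else NA_real_
    data.frame(tx_id = row$tx_id,
               aa_length = if (is.null(orf)) NA_integer_ else orf$aa_length,
               orf_start = if (is.null(orf)) NA_integer_ else orf$start_nt,
               orf_gt100 = orf_exceeds(orf, 100L),
               orf_fraction = pfrac, stringsAsFactors = FALSE)
  })
  orf_rows <- Filter(Negate(is.null), orf_rows)
  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(tx_id = character(), aa_length = integer(),
               orf_start = integer(), orf_gt100 = logical(),
               orf_fraction = numeric())
  rownames(orfs) <- NULL

  fusions <- detect_fusions(classified, txs, cohort$genes, cohort$pg_records,
                            cohort$genome)

  dnds <- run_dnds_stage(classified, orfs, txs, cohort)

  labels <- data.frame(
    tx_id = classified$tx_id,
    label = vapply(seq_len(nrow(classified)), function(i) {
      row <- classified[i, ]
      if (row$is_pseudogene_transcript && row$retrocopy_confirmed) {
        if (is.na(row$independence)) return("other")
        if (row$independence == "dependent") return("dependent_intronic")
        if (row$orientation == "sense") return("independent_sense")
        return("independent_antisense")
      }
      if (row$assigned_biotype == "protein_coding") {
        if (row$tx_id %in% fusions$tx_id) return("fusion")
        return("parent_mRNA")
      }
      "other"
    }, character(1)), stringsAsFactors = FALSE)

  summary <- summarize_cohort(classified, features = features, orfs = orfs,
                              dnds = dnds$summary)
  list(classified = classified, features = features, orfs = orfs,
       fusions = fusions, dnds_table = dnds$table,
       dnds_estimates = dnds$estimates, dnds_summary = dnds$summary,
       labels = labels, summary = summary)
}

# Selection stage: independent sense pseudogene transcripts with an ORF
# are compared against their pseudogene's orthologous window.
run_dnds_stage <- function(classified, orfs, txs, cohort) {
  empty <- data.frame(tx_id = character(), pseudogene_id = character(),
                      S = numeric(), N = numeric(), Sd = numeric(),
                      Nd = numeric(), pS = numeric(), pN = numeric(),
                      dS = numeric(), dN = numeric(), omega = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  wins <- cohort$ortholog_windows
  if (is.null(wins) || !length(wins))
    return(list(table = empty, estimates = list(), summary = dnds_summary(list())))
  cand <- classified[classified$is_pseudogene_transcript &
                       !is.na(classified$independence) &
                       classified$independence == "independent" &
                       classified$orientation == "sense", , drop = FALSE]
  rows <- list(); ests <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    o <- orfs[orfs$tx_id == row$tx_id, , drop = FALSE]
    if (nrow(o) == 0L || is.na(o$aa_length[1L])) next
    win <- wins[[row$assigned_gene_id]]
    if (is.null(win) || is.na(win)) next
    tx <- txs[[row$tx_id]]
    seq <- tx_spliced_seq(tx, cohort$genome)
    orf <- find_longest_orf(seq)
    cdna <- substring(seq, orf$start_nt + 1L, orf$end_nt - 3L)  # stop stripped
    add <- function(status, est = NULL) {
      rows[[length(rows) + 1L]] <<- data.frame(
        tx_id = row$tx_id, pseudogene_id = row$assigned_gene_id,
        S = if (is.null(est)) NA_real_ else est$S,
        N = if (is.null(est)) NA_real_ else est$N,
        Sd = if (is.null(est)) NA_real_ else est$Sd,
        Nd = if (is.null(est)) NA_real_ else est$Nd,
        pS = if (is.null(est)) NA_real_ else est$pS,
        pN = if (is.null(est)) NA_real_ else est$pN,
        dS = if (is.null(est)) NA_real_ else est$dS,
        dN = if (is.null(est)) NA_real_ else est$dN,
        omega = if (is.null(est)) NA_real_ else est$omega,
        status = status, stringsAsFactors = FALSE)
    }
    loc <- locate_ortholog_cdna(cdna, win)
    if (is.null(loc)) { add("no_ortholog"); next }
    sub <- loc$aligned_target_subseq
    if (!check_divisible_by_three(sub)) { add("not_divisible"); next }
    p1 <- translate_cdna(cdna)
    p2 <- translate_cdna(sub)
    if (grepl("*", p1, fixed = TRUE) || grepl("*", p2, fixed = TRUE)) {
      add("ortholog_disrupted"); next
    }
    aln <- global_protein_align(p1, p2)
    cal <- thread_codons(aln, cdna, sub)
    est <- tryCatch(ng86_dnds(cal), error = function(e) NULL)
    if (is.null(est)) { add("no_ortholog"); next }
    status <- if (est$n_diff < 1L || is.na(est$dS) || est$dS == 0)
      "insufficient_diversity"
    else if (is.na(est$omega)) "undefined" else "defined"
    if (status == "insufficient_diversity") {
      est$omega <- NA_real_  # excluded from the summary denominator
    } else {
      ests[[length(ests) + 1L]] <- est
    }
    add(status, est)
  }
  table <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(table) <- NULL
  list(table = table, estimates = ests, summary = dnds_summary(ests))
}

#' Load an emitted simulation directory
#'
#' Reconstructs the in-memory cohort from the files written by
#' [emit_simulation()] (or equivalently-shaped real data): genome FASTA,
#' annotation GTF, retrocopy BED6 with a parent-linkage TSV, transcript
#' BED12 with an abundance TSV, CAGE BED/bedGraph and ortholog FASTA.
#'
#' @param dir Directory containing the files.
#' @return List shaped like a `"pseudogene_sim"` (without truth unless
#'   present).
#' @export
load_simulation <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  genes <- read_gtf(file.path(dir, "annotation.gtf"))
  retro <- read_bed(file.path(dir, "retro.bed"))
  links <- read_tsv_report(file.path(dir, "parents.tsv"))
  pg_records <- list()
  for (i in seq_len(nrow(retro))) {
    pid <- retro$name[i]
    if (!pid %in% names(genes)) next
    parent <- links$parent_gene_id[match(pid, links$pseudogene_id)]
    pg_records[[pid]] <- pseudogene_record(
      genes[[pid]], parent_gene_id = parent,
      retro_interval = genomic_interval(retro$chrom[i], retro$start[i],
                                        retro$end[i], retro$strand[i]))
  }
  txs <- read_bed(file.path(dir, "transcripts.bed"), blocked = TRUE)
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  ab_path <- file.path(dir, "abundance.tsv")
  if (file.exists(ab_path)) {
    ab <- read_tsv_report(ab_path)
    for (id in names(txs)) {
      m <- match(id, ab$tx_id)
      if (!is.na(m)) txs[[id]]$fl_read_count <- as.integer(ab$fl_read_count[m])
    }
  }
  peaks <- read_bed(file.path(dir, "cage_peaks.bed"))
  sig_path <- file.path(dir, "cage_signal.bedGraph")
  signal <- if (file.exists(sig_path)) read_bedgraph(sig_path) else NULL
  orth_path <- file.path(dir, "ortholog_windows.fa")
  orth <- if (file.exists(orth_path)) read_fasta(orth_path) else NULL
  truth_path <- file.path(dir, "truth_transcripts.tsv")
  truth <- if (file.exists(truth_path))
    list(transcripts = read_tsv_report(truth_path)) else NULL
  list(genome = genome, genes = genes, pg_records = pg_records,
       retro_track = if (nrow(retro)) interval_set(retro$chrom, retro$start,
                                                   retro$end)
       else interval_set(),
       transcripts = txs, cage_peaks = peaks, cage_signal = signal,
       ortholog_windows = orth, truth = truth)
}

#' Run the pipeline over an emitted directory
#'
#' @param dir Directory written by [emit_simulation()].
#' @param ... Passed to [analyze_cohort()].
#' @return The [analyze_cohort()] result, with `concordance_pct` added
#'   when a truth manifest is present.
#' @export
run_pipeline <- function(dir, ...) {
  cohort <- load_simulation(dir)
  res <- analyze_cohort(cohort, ...)
  if (!is.null(cohort$truth))
    res$concordance_pct <- label_concordance(res$labels, cohort$truth$transcripts)
  res
}

#' Fraction of predicted labels matching planted truth
#'
#' @param labels data.frame with `tx_id`, `label` (pipeline predictions).
#' @param truth_tx Truth-manifest transcript table with `tx_id`, `label`.
#' @return Percentage in `[0, 100]` over transcripts present in both.
#' @export
label_concordance <- function(labels, truth_tx) {
  m <- match(labels$tx_id, truth_tx$tx_id)
  ok <- !is.na(m)
  if (!any(ok)) return(NA_real_)
  100 * mean(labels$label[ok] == truth_tx$label[m[ok]])
}
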