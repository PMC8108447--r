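test_that("make_parent_gene builds the configured structure deterministically", {
  cfg <- sim_config(exons_per_gene = c(3L, 3L), cds_length_codons = c(100L, 100L))
  g1 <- make_parent_gene(cfg, seed = 5L)
  expect_equal(nrow(g1$exons), 3L)
  expect_equal(g1$aa_length, 100L)
  cds <- substring(g1$mrna, g1$utr5_len + 1L, g1$utr5_len + 3L * 101L)
  prot <- translate_cdna(cds)
  expect_equal(nchar(prot), 101L)
  expect_equal(substring(prot, 101L, 101L), "*")
  expect_false(grepl("*", substring(prot, 1L, 100L), fixed = TRUE))
  expect_equal(substring(prot, 1L, 1L), "M")

  g2 <- make_parent_gene(cfg, seed = 5L)
  expect_identical(g1, g2)
  g3 <- make_parent_gene(cfg, seed = 6L)
  expect_false(identical(g1$mrna, g3$mrna))
})

test_that("spliced parent transcripts carry exactly the annotated ORF", {
  cfg <- sim_config(n_parent_genes = 6L, n_pseudogenes = 0L, fusion_count = 0L)
  sim <- simulate_pseudogene_cohort(cfg, seed = 21L)
  strands <- vapply(sim$genes, function(g) g$transcripts[[1]]$strand,
                    character(1))
  expect_true(all(strands %in% c("+", "-")))
  for (g in sim$genes) {
    tx <- g$transcripts[[1]]
    orf <- find_longest_orf(tx_spliced_seq(tx, sim$genome))
    # an in-frame upstream ATG in the 5' UTR may extend the ORF, so the
    # annotated length is a lower bound; exact equality is checked in the
    # no-reinitiation fixture
    expect_gte(orf$aa_length, parent_orf_length(g))
    expect_lte(orf$aa_length - parent_orf_length(g), 60L)
  }
})

test_that("a divergence-0 retrocopy is an exact mRNA copy with a polyA tract", {
  cfg <- sim_config(n_parent_genes = 4L, n_pseudogenes = 4L, divergence = 0,
                    indel_rate = 0, frameshift_fraction = 0, fusion_count = 0L,
                    intronic_insertion_fraction = 0, antisense_fraction = 0,
                    novel_exon_fraction = 0, txs_per_pseudogene = c(1L, 1L),
                    fl_count_distribution = list(min = 2L, prob = 0.5))
  sim <- simulate_pseudogene_cohort(cfg, seed = 31L)
  for (pid in names(sim$pg_records)) {
    rec <- sim$pg_records[[pid]]
    ri <- rec$retro_interval
    body <- substring(sim$genome[[ri$chrom]], ri$start + 1L, ri$end)
    if (ri$strand == "-") body <- pseudotx:::revcomp(body)
    parent_tx <- sim$genes[[rec$parent_gene_id]]$transcripts[[1]]
    mrna <- tx_spliced_seq(parent_tx, sim$genome)
    # the copy may differ from today's parent only inside the planted
    # 3'-end polyA-motif window; compare the first 80% of the mRNA
    n <- floor(0.8 * nchar(mrna))
    expect_equal(substring(body, 1L, n), substring(mrna, 1L, n))
    tail_seq <- substring(body, nchar(body) - 7L, nchar(body))
    expect_equal(tail_seq, strrep("A", 8L))  # polyA tract end
  }
})

test_that("the simulator is a pure function of (config, seed)", {
  cfg <- sim_config(n_parent_genes = 5L, n_pseudogenes = 4L, fusion_count = 1L)
  s1 <- simulate_pseudogene_cohort(cfg, seed = 77L)
  s2 <- simulate_pseudogene_cohort(cfg, seed = 77L)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pseudogene_cohort(cfg, seed = 78L)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("same seed emits byte-identical files that re-parse losslessly", {
  cfg <- sim_config(n_parent_genes = 5L, n_pseudogenes = 4L, fusion_count = 1L)
  sim <- simulate_pseudogene_cohort(cfg, seed = 19L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_simulation(sim, d1)
  emit_simulation(simulate_pseudogene_cohort(cfg, seed = 19L), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- load_simulation(d1)
  expect_identical(back$genome, sim$genome)
  for (id in names(sim$transcripts))
    expect_equal(back$transcripts[[id]]$exons, sim$transcripts[[id]]$exons)
  for (id in names(sim$genes))
    expect_equal(back$genes[[id]]$transcripts[[1]]$exons,
                 sim$genes[[id]]$transcripts[[1]]$exons)
  expect_equal(back$pg_records[[1]]$parent_gene_id,
               sim$pg_records[[1]]$parent_gene_id)
})

test_that("n_pseudogenes = 0 yields no pseudogene transcripts", {
  cfg <- sim_config(n_parent_genes = 4L, n_pseudogenes = 0L, fusion_count = 0L)
  sim <- simulate_pseudogene_cohort(cfg, seed = 3L)
  res <- analyze_cohort(sim)
  expect_equal(sum(res$classified$is_pseudogene_transcript), 0L)
})

test_that("forced intronic insertion produces dependent transcripts", {
  cfg <- sim_config(n_parent_genes = 8L, n_pseudogenes = 4L, divergence = 0,
                    indel_rate = 0, frameshift_fraction = 0, fusion_count = 0L,
                    intronic_insertion_fraction = 1, cage_jitter_sd = 0,
                    fl_count_distribution = list(min = 2L, prob = 0.5))
  sim <- simulate_pseudogene_cohort(cfg, seed = 41L)
  expect_true(all(sim$truth$pseudogenes$intronic))
  res <- analyze_cohort(sim)
  pg_rows <- res$classified[res$classified$is_pseudogene_transcript, ]
  expect_true(nrow(pg_rows) > 0L)
  expect_true(all(pg_rows$independence == "dependent"))
  # and each transcript is genuinely intronic within its host gene
  for (i in seq_len(nrow(pg_rows))) {
    host_id <- sim$truth$pseudogenes$host_gene_id[
      match(pg_rows$assigned_gene_id[i], sim$truth$pseudogenes$pseudogene_id)]
    expect_true(is_intronic(sim$transcripts[[pg_rows$tx_id[i]]],
                            sim$genes[[host_id]]))
  }
})

test_that("planted frameshifts cap the recoverable ORF at the planted fraction", {
  cfg <- sim_config(n_parent_genes = 20L, n_pseudogenes = 200L, divergence = 0,
                    indel_rate = 0, frameshift_fraction = 0.3,
                    fusion_count = 0L, intronic_insertion_fraction = 0,
                    antisense_fraction = 0, novel_exon_fraction = 0,
                    txs_per_pseudogene = c(1L, 1L), cage_jitter_sd = 0,
                    fl_count_distribution = list(min = 2L, prob = 0.5),
                    disable_reinitiation = TRUE)
  sim <- simulate_pseudogene_cohort(cfg, seed = 101L)
  res <- analyze_cohort(sim)
  tp <- sim$truth$pseudogenes
  orfs <- res$orfs
  cls <- res$classified
  frac <- setNames(orfs$orf_fraction, orfs$tx_id)
  pg_of_tx <- setNames(cls$assigned_gene_id, cls$tx_id)
  shifted <- 0L
  for (tx_id in names(frac)) {
    row <- tp[match(pg_of_tx[[tx_id]], tp$pseudogene_id), ]
    if (row$frameshift) {
      shifted <- shifted + 1L
      # no re-initiation allowed: the fraction is bounded by the planted
      # disruption point exactly
      expect_lte(frac[[tx_id]], row$frameshift_fraction)
      expect_lt(frac[[tx_id]], 0.9)
    } else {
      expect_equal(frac[[tx_id]], 1.0)
    }
  }
  # the ORF stage recovers the planted frameshift fraction
  recovered <- mean(frac < 0.9)
  planted <- mean(tp$frameshift)
  expect_equal(recovered, planted)
  expect_lt(abs(planted - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(tp)) + 0.01)
  expect_gt(shifted, 0L)
})

test_that("CAGE support degrades monotonically with peak jitter", {
  supported_frac <- function(sd, seed) {
    cfg <- sim_config(n_parent_genes = 6L, n_pseudogenes = 12L, divergence = 0,
                      indel_rate = 0, frameshift_fraction = 0,
                      fusion_count = 0L, intronic_insertion_fraction = 0,
                      cage_jitter_sd = sd, n_background_peaks = 0L,
                      txs_per_pseudogene = c(2L, 2L),
                      fl_count_distribution = list(min = 2L, prob = 0.5))
    sim <- simulate_pseudogene_cohort(cfg, seed = seed)
    res <- analyze_cohort(sim)
    mean(res$features$cage_supported)
  }
  seeds <- 1:3
  f0 <- mean(vapply(seeds, function(s) supported_frac(0, s), numeric(1)))
  f300 <- mean(vapply(seeds, function(s) supported_frac(300, s), numeric(1)))
  expect_equal(f0, 1)      # zero jitter: every TSS inside its peak
  expect_lt(f300, 1)       # heavy jitter: support drops
})

test_that("the CAGE meta-profile of simulated signal peaks at the TSS", {
  cfg <- sim_config(n_parent_genes = 6L, n_pseudogenes = 10L, divergence = 0,
                    indel_rate = 0, cage_jitter_sd = 0, fusion_count = 0L,
                    n_background_peaks = 0L)
  sim <- simulate_pseudogene_cohort(cfg, seed = 55L)
  tt <- sim$truth$transcripts
  prof <- cage_metaprofile(
    data.frame(chrom = "chr1", tss = tt$tss, strand = tt$strand),
    sim$cage_signal, flank = 500L, bin = 10L)
  expect_true(which.max(prof) %in% c(50L, 51L))
})
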