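test_that("filter_by_support applies the two-read floor", {
  txs <- list(mk_tx("a", 0L, 10L, fl = 1L), mk_tx("b", 0L, 10L, fl = 2L),
              mk_tx("c", 0L, 10L, fl = 3L))
  expect_length(filter_by_support(txs, 2L), 2L)
  expect_length(filter_by_support(txs, 1L), 3L)
  expect_length(filter_by_support(list(), 2L), 0L)
  expect_equal(vapply(filter_by_support(txs, 2L), `[[`, character(1), "id"),
               c("b", "c"))
})

test_that("assign_transcript takes the maximal exonic overlap with tie-breaks", {
  pg <- mk_gene("psg1", 0L, 1000L, biotype = "processed_pseudogene")
  coding <- mk_gene("gene1", 900L, 1200L)
  tx <- mk_tx("t", 100L, 1000L)
  asn <- assign_transcript(tx, list(coding, pg))
  expect_equal(asn$gene_id, "psg1")
  expect_equal(asn$overlap_bp, 900L)

  far <- mk_tx("t", 5000L, 5100L)
  expect_equal(assign_transcript(far, list(coding, pg)),
               list(gene_id = "none", overlap_bp = 0L))

  # exact tie: pseudogene biotype preferred
  a <- mk_gene("aaa", 0L, 100L)
  b <- mk_gene("zzz", 0L, 100L, biotype = "processed_pseudogene")
  tie_tx <- mk_tx("t", 0L, 100L)
  expect_equal(assign_transcript(tie_tx, list(a, b))$gene_id, "zzz")
  # both coding: lexicographically smallest id
  b2 <- mk_gene("bbb", 0L, 100L)
  expect_equal(assign_transcript(tie_tx, list(b2, a))$gene_id, "aaa")
})

test_that("confirm_retrocopy needs one exonic base over the retro interval", {
  retro <- interval_set("chr1", 100L, 200L)
  expect_true(confirm_retrocopy(mk_tx("t", 199L, 300L), retro))
  # transcript touching only a novel 5' exon upstream of the copy
  expect_false(confirm_retrocopy(mk_tx("t", c(0L, 210L), c(50L, 300L), "+"),
                                 retro))
  expect_false(confirm_retrocopy(mk_tx("t", 100L, 200L), interval_set()))
})

test_that("independence needs strictly greater overlap and non-intronic position", {
  pgene <- mk_gene("psg1", 1000L, 2000L, biotype = "processed_pseudogene")
  rec <- pseudogene_record(pgene, "parent1",
                           genomic_interval("chr1", 1000L, 2000L, "+"))
  expect_equal(classify_independence(mk_tx("t", 1000L, 2000L), rec, list()),
               "independent")

  # pseudogene inside a coding gene's intron
  host <- mk_gene("host", c(500L, 2500L), c(600L, 2600L))
  expect_equal(classify_independence(mk_tx("t", 1000L, 2000L), rec,
                                     list(host)), "dependent")

  # coding-exon overlap (300 bp) exceeds pseudogene overlap (200 bp)
  pg2 <- mk_gene("psg2", 0L, 200L, biotype = "processed_pseudogene")
  rec2 <- pseudogene_record(pg2, "parent1",
                            genomic_interval("chr1", 0L, 200L, "+"))
  coding <- mk_gene("big", 200L, 1000L)
  tx <- mk_tx("t", 0L, 500L)
  expect_equal(classify_independence(tx, rec2, list(coding)), "dependent")

  # another pseudogene never breaks independence
  other_pg <- mk_gene("psg3", 1000L, 2000L, biotype = "processed_pseudogene")
  expect_equal(classify_independence(mk_tx("t", 1000L, 2000L), rec,
                                     list(other_pg)), "independent")
})

test_that("independence is monotone in the pseudogene overlap", {
  coding <- mk_gene("big", 600L, 900L)
  verdicts <- vapply(c(100L, 200L, 300L, 301L, 600L, 1200L), function(pg_end) {
    pgene <- mk_gene("psg", 0L, pg_end, biotype = "processed_pseudogene")
    rec <- pseudogene_record(pgene, "p",
                             genomic_interval("chr1", 0L, pg_end, "+"))
    classify_independence(mk_tx("t", 0L, 1500L), rec, list(coding))
  }, character(1))
  # strict inequality at the boundary, then monotone: growing pseudogene
  # overlap never flips independent back to dependent
  expect_equal(verdicts[1:3], rep("dependent", 3L))
  expect_equal(verdicts[4:6], rep("independent", 3L))
})

test_that("orientation compares transcript strand to the retrocopy strand", {
  pgene <- mk_gene("psg1", 0L, 100L, "+", biotype = "processed_pseudogene")
  rec <- pseudogene_record(pgene, "p", genomic_interval("chr1", 0L, 100L, "+"))
  expect_equal(classify_orientation(mk_tx("t", 0L, 100L, "+"), rec), "sense")
  expect_equal(classify_orientation(mk_tx("t", 0L, 100L, "-"), rec), "antisense")
  rec_minus <- pseudogene_record(
    mk_gene("psg2", 0L, 100L, "-", biotype = "processed_pseudogene"), "p",
    genomic_interval("chr1", 0L, 100L, "-"))
  expect_equal(classify_orientation(mk_tx("t", 0L, 100L, "+"), rec_minus),
               "antisense")
  rec_dot <- rec
  rec_dot$retro_interval$strand <- "."
  expect_error(classify_orientation(mk_tx("t", 0L, 100L, "+"), rec_dot),
               "undefined")
})

test_that("orientation is an involution under transcript strand flip", {
  pgene <- mk_gene("psg1", 0L, 100L, "+", biotype = "processed_pseudogene")
  rec <- pseudogene_record(pgene, "p", genomic_interval("chr1", 0L, 100L, "+"))
  for (s in c("+", "-")) {
    tx <- mk_tx("t", 0L, 100L, s)
    flipped <- mk_tx("t", 0L, 100L, if (s == "+") "-" else "+")
    expect_false(classify_orientation(tx, rec) ==
                   classify_orientation(flipped, rec))
  }
})

test_that("junction sharing requires exact coordinates", {
  ref <- mk_tx("ref", c(0L, 200L, 500L), c(100L, 300L, 600L))
  same <- mk_tx("t", c(0L, 200L, 500L), c(100L, 300L, 600L))
  expect_equal(shared_junctions(same, list(ref)), list(shared = TRUE, count = 2L))
  shifted <- mk_tx("t", c(0L, 201L), c(100L, 300L))
  expect_equal(shared_junctions(shifted, list(ref))$count, 0L)
  mono <- mk_tx("t", 0L, 600L)
  expect_equal(shared_junctions(mono, list(ref)), list(shared = FALSE, count = 0L))
  # strand is part of the junction key
  anti <- mk_tx("t", c(0L, 200L), c(100L, 300L), "-")
  expect_false(shared_junctions(anti, list(ref))$shared)
})

test_that("classify_transcripts integrates assignment, independence and junctions", {
  pgene <- mk_gene("psg1", 1000L, 2000L, "+", biotype = "processed_pseudogene")
  parent <- mk_gene("gene1", c(5000L, 5500L), c(5200L, 5800L), "+",
                    cds = data.frame(start = 5050L, end = 5200L))
  genes <- list(psg1 = pgene, gene1 = parent)
  recs <- list(psg1 = pseudogene_record(
    pgene, "gene1", genomic_interval("chr1", 1000L, 2000L, "+")))
  retro <- interval_set("chr1", 1000L, 2000L)
  txs <- list(
    s = mk_tx("s", 1000L, 2000L, "+", fl = 3L),
    a = mk_tx("a", 1100L, 1900L, "-", fl = 2L),
    weak = mk_tx("weak", 1000L, 2000L, "+", fl = 1L),
    par = mk_tx("par", c(5000L, 5500L), c(5200L, 5800L), "+", fl = 5L))
  out <- classify_transcripts(txs, genes, recs, retro)
  expect_equal(nrow(out), 3L)  # 'weak' filtered
  expect_false("weak" %in% out$tx_id)
  s <- out[out$tx_id == "s", ]
  expect_true(s$is_pseudogene_transcript)
  expect_true(s$retrocopy_confirmed)
  expect_equal(s$independence, "independent")
  expect_equal(s$orientation, "sense")
  expect_equal(out[out$tx_id == "a", "orientation"], "antisense")
  par_row <- out[out$tx_id == "par", ]
  expect_equal(par_row$assigned_biotype, "protein_coding")
  expect_true(par_row$shares_reference_junction)
})
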