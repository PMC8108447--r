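test_that("translate_cdna follows the standard code with X for ambiguity", {
  expect_equal(translate_cdna("ATGTAA"), "M*")
  expect_equal(translate_cdna("ATGGATGAA"), "MDE")
  expect_error(translate_cdna("ATGGA"), "divisible")
  expect_equal(translate_cdna("ATGNNN"), "MX")
})

test_that("find_longest_orf requires ATG..stop and prefers 5'-most ties", {
  expect_null(find_longest_orf("CCCCCCCCCCCC"))
  orf <- find_longest_orf("AAATGGCCTAA")
  expect_equal(orf$protein, "MA")
  expect_equal(orf$aa_length, 2L)
  expect_equal(orf$start_nt, 2L)
  expect_equal(orf$end_nt, 11L)

  # open-ended ORF (no stop) is not called
  expect_null(find_longest_orf("ATGGCCGCCGCC"))

  # two equal-length ORFs in different frames: the 5'-most wins
  tie <- paste0("ATGGCCTAA", "C", "ATGGATTGA")
  orf_t <- find_longest_orf(tie)
  expect_equal(orf_t$start_nt, 0L)
  expect_equal(orf_t$aa_length, 2L)
})

test_that("find_longest_orf matches brute-force enumeration on short sequences", {
  withr::with_seed(31, {
    for (i in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1L),
                        replace = TRUE), collapse = "")
      got <- find_longest_orf(s)
      want <- bf_longest_orf(s)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$aa_length, want$aa_length)
        expect_equal(got$start_nt, want$start_nt)
        expect_equal(got$end_nt, want$end_nt)
      }
    }
  })
})

test_that("ORF records translate cleanly with a single terminal stop", {
  withr::with_seed(37, {
    for (i in 1:50) {
      s <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
      orf <- find_longest_orf(s)
      if (is.null(orf)) next
      full <- translate_cdna(substring(s, orf$start_nt + 1L, orf$end_nt))
      expect_equal(full, paste0(orf$protein, "*"))
      expect_false(grepl("*", orf$protein, fixed = TRUE))
      expect_equal(orf$aa_length, (orf$end_nt - orf$start_nt) / 3L - 1L)
    }
  })
})

test_that("orf_exceeds is strict at the 100 aa boundary", {
  orf100 <- list(aa_length = 100L)
  orf101 <- list(aa_length = 101L)
  expect_false(orf_exceeds(orf100))
  expect_true(orf_exceeds(orf101))
  expect_false(orf_exceeds(NULL))
})

test_that("parent_orf_fraction is a capped length ratio", {
  expect_equal(parent_orf_fraction(list(aa_length = 90L), 90L), 1)
  expect_equal(parent_orf_fraction(list(aa_length = 45L), 90L), 0.5)
  expect_equal(parent_orf_fraction(list(aa_length = 120L), 100L), 1)
  expect_equal(parent_orf_fraction(NULL, 100L), 0)
  expect_error(parent_orf_fraction(list(aa_length = 10L), 0L))
})

test_that("detect_fusions counts pseudogene-derived codons by 2-of-3 majority", {
  # 60-codon ORF; the last 20 codons sit inside the retro interval
  withr::with_seed(41, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA", "ATG"))
    orf <- paste0("ATG", paste(sample(sense, 59L, replace = TRUE),
                               collapse = ""), "TAA")
  })
  g <- c(chr1 = paste0(strrep("C", 100), orf, strrep("C", 100)))
  tx <- mk_tx("f", 100L, 100L + nchar(orf), "+")
  txs <- list(f = tx)
  classified <- data.frame(tx_id = "f", assigned_gene_id = "host",
                           assigned_biotype = "protein_coding",
                           stringsAsFactors = FALSE)
  mk_rec <- function(start, end, strand = "+") {
    pg <- mk_gene("psg", start, end, strand, biotype = "processed_pseudogene")
    pseudogene_record(pg, "par", genomic_interval("chr1", start, end, strand))
  }
  # retro interval = last 20 codons of the ORF (coding part, before stop)
  r_start <- 100L + 3L * 40L
  recs <- list(psg = mk_rec(r_start, 100L + 3L * 60L))
  fus <- detect_fusions(classified, txs, list(), recs, g)
  expect_equal(fus$codons_from_pseudogene, 20L)
  expect_equal(fus$pseudogene_strand_relative, "sense")

  # boundary codon with 2 of 3 bases inside still counts
  recs2 <- list(psg = mk_rec(r_start + 1L, 100L + 3L * 60L))
  expect_equal(detect_fusions(classified, txs, list(), recs2,
                              g)$codons_from_pseudogene, 20L)
  # only 1 of 3 bases inside: boundary codon excluded
  recs3 <- list(psg = mk_rec(r_start + 2L, 100L + 3L * 60L))
  expect_equal(detect_fusions(classified, txs, list(), recs3,
                              g)$codons_from_pseudogene, 19L)

  # antisense-derived fusion is still detected, with relative strand recorded
  recs4 <- list(psg = mk_rec(r_start, 100L + 3L * 60L, strand = "-"))
  fus4 <- detect_fusions(classified, txs, list(), recs4, g)
  expect_equal(fus4$codons_from_pseudogene, 20L)
  expect_equal(fus4$pseudogene_strand_relative, "antisense")

  # no overlap with any retrocopy: no record
  recs5 <- list(psg = mk_rec(5000L, 6000L))
  expect_equal(nrow(detect_fusions(classified, txs, list(), recs5, g)), 0L)
})
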