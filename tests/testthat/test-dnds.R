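test_that("ng86_dnds reproduces hand-enumerated worked examples", {
  # identical sequences: no differences, omega undefined
  est0 <- ng86_dnds(list(rows = c("ATGGAT", "ATGGAT")))
  expect_equal(est0$Sd, 0)
  expect_equal(est0$Nd, 0)
  expect_equal(est0$dS, 0)
  expect_equal(est0$dN, 0)
  expect_true(is.na(est0$omega))

  # single nonsynonymous difference: dS = 0, omega undefined
  est1 <- ng86_dnds(list(rows = c("ATGGAT", "ATGGAA")))
  expect_equal(est1$Sd, 0)
  expect_equal(est1$Nd, 1)
  expect_equal(est1$pS, 0)
  expect_true(is.na(est1$omega))

  # single synonymous difference: S-bar = 5/3 per sequence, omega = 0
  est2 <- ng86_dnds(list(rows = c("ATGGGAAAATTT", "ATGGGGAAATTT")))
  expect_equal(est2$Sd, 1)
  expect_equal(est2$Nd, 0)
  expect_equal(est2$S, 5 / 3)
  expect_equal(est2$pN, 0)
  expect_equal(est2$dN, 0)
  expect_equal(est2$dS, -0.75 * log(1 - 4 / 3 * (1 / (5 / 3))))
  expect_equal(est2$omega, 0)
})

test_that("gap, ambiguous and stop codon columns are excluded", {
  est <- ng86_dnds(list(rows = c("ATG---GANGAT", "ATGAAAGATGAT")))
  expect_equal(est$n_codons, 2L)  # ATG and GAT only
  expect_error(ng86_dnds(list(rows = c("---", "AAA"))), "usable")
})

test_that("per-codon site counts sum to 3 for every sense codon", {
  sites <- pseudotx:::ng86_site_table()
  expect_length(sites, 61L)
  # S_codon + N_codon = 3 by definition of the per-position fractions;
  # verify S_codon independently from all 9 single-base changes
  for (cod in names(sites)) {
    chars <- strsplit(cod, "", fixed = TRUE)[[1]]
    syn <- 0
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      alt <- chars; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (!altc %in% c("TAA", "TAG", "TGA") &&
          Biostrings::GENETIC_CODE[[altc]] == Biostrings::GENETIC_CODE[[cod]])
        syn <- syn + 1
    }
    expect_equal(sites[[cod]], syn / 3)
    expect_equal(sites[[cod]] + (3 - sites[[cod]]), 3)
  }
})

test_that("pathway averaging matches brute-force ordering enumeration", {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  withr::with_seed(81, {
    pairs <- cbind(sample(sense, 400L, replace = TRUE),
                   sample(sense, 400L, replace = TRUE))
  })
  for (k in seq_len(nrow(pairs))) {
    got <- pseudotx:::ng86_pair_diffs(pairs[k, 1], pairs[k, 2])
    want <- bf_pair_diffs(pairs[k, 1], pairs[k, 2])
    expect_equal(got, want, info = paste(pairs[k, ], collapse = "/"))
  }
})

test_that("ng86 dN and dS agree with an independent reference implementation", {
  skip_if_not(nzchar(Sys.which("python")), "python not available")
  cds <- random_sense_cds(300L, seed = 42L)
  div <- simulate_codon_divergence(cds, 0.15, 0.5, seed = 9L)
  est <- ng86_dnds(list(rows = c(cds, div)))
  script <- paste(
    "import warnings; warnings.filterwarnings('ignore')",
    "from Bio.codonalign.codonseq import CodonSeq, cal_dn_ds",
    sprintf("dn, ds = cal_dn_ds(CodonSeq('%s'), CodonSeq('%s'), method='NG86')",
            cds, div),
    "print(repr(dn)); print(repr(ds))", sep = "\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 2L, "reference NG86 implementation unavailable")
  expect_equal(est$dN, as.numeric(out[1]), tolerance = 1e-9)
  expect_equal(est$dS, as.numeric(out[2]), tolerance = 1e-9)
})

test_that("jukes-cantor correction is undefined at saturation", {
  expect_true(is.na(pseudotx:::jc_correct(0.75)))
  expect_true(is.na(pseudotx:::jc_correct(0.9)))
  expect_equal(pseudotx:::jc_correct(0), 0)
})

test_that("dnds_summary counts purifying estimates and takes the median", {
  mk <- function(om) structure(list(omega = om), class = "dnds_estimate")
  s <- dnds_summary(list(mk(0.2), mk(0.5), mk(1.5)))
  expect_equal(s$n_defined, 3L)
  expect_equal(s$n_purifying, 2L)
  expect_equal(s$median_omega, 0.5)

  s0 <- dnds_summary(list(mk(NA_real_), mk(NA_real_)))
  expect_equal(s0$n_defined, 0L)
  expect_equal(s0$n_purifying, 0L)
  expect_true(is.na(s0$median_omega))

  # even count: midpoint of the central pair
  s4 <- dnds_summary(list(mk(0.1), mk(0.3), mk(0.5), mk(0.9)))
  expect_equal(s4$median_omega, 0.4)
})

test_that("simulate_codon_divergence honours rate, selection and seed", {
  cds <- random_sense_cds(100L, seed = 5L)
  expect_equal(simulate_codon_divergence(cds, 0, 0.5, seed = 1L), cds)

  forced <- simulate_codon_divergence(cds, 0.4, 0, seed = 2L)
  expect_equal(translate_cdna(forced), translate_cdna(cds))
  expect_false(forced == cds)  # synonymous changes did occur

  expect_identical(simulate_codon_divergence(cds, 0.3, 0.5, seed = 3L),
                   simulate_codon_divergence(cds, 0.3, 0.5, seed = 3L))
  expect_false(identical(simulate_codon_divergence(cds, 0.3, 0.5, seed = 3L),
                         simulate_codon_divergence(cds, 0.3, 0.5, seed = 4L)))
  # no stop codon ever appears
  div <- simulate_codon_divergence(cds, 1, 1, seed = 6L)
  expect_false(grepl("*", translate_cdna(div), fixed = TRUE))
})
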