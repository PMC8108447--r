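# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction, a
# selection summary, and a codon-level divergence simulator used for
# parameter-recovery checks.

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

# Per-codon expected synonymous sites (NG86): at each position, the
# fraction of the three possible changes that preserve the amino acid;
# changes creating a stop codon count as nonsynonymous.
.ng86_env <- new.env(parent = emptyenv())

ng86_site_table <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env$sites)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sites <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    chars <- strsplit(cod, "", fixed = TRUE)[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[pos])) {
        alt <- chars; alt[pos] <- b
        altc <- paste(alt, collapse = "")
        if (!altc %in% STOP_CODONS && codon_aa(altc) == codon_aa(cod))
          s <- s + 1 / 3
      }
    }
    sites[cod] <- s
  }
  .ng86_env$sites <- sites
  sites
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all mutational pathways (orderings of the differing
# positions). Pathways passing through a stop codon are excluded unless
# every pathway does, in which case all are averaged.
ng86_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a1 != a2)
  perms <- if (length(dpos) == 1L) list(dpos) else {
    prm <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in prm(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    prm(dpos)
  }
  paths <- lapply(perms, function(ord) {
    cur <- a1; sd <- 0; nd <- 0; through_stop <- FALSE
    for (j in seq_along(ord)) {
      nxt <- cur; nxt[ord[j]] <- a2[ord[j]]
      curc <- paste(cur, collapse = ""); nxtc <- paste(nxt, collapse = "")
      if (codon_aa(curc) == codon_aa(nxtc)) sd <- sd + 1 else nd <- nd + 1
      if (j < length(ord) && nxtc %in% STOP_CODONS) through_stop <- TRUE
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  })
  ok <- Filter(function(p) !p$through_stop, paths)
  if (!length(ok)) ok <- paths
  c(sd = mean(vapply(ok, `[[`, numeric(1), "sd")),
    nd = mean(vapply(ok, `[[`, numeric(1), "nd")))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # correction undefined
  -0.75 * log(1 - 4 * p / 3) + 0   # + 0 normalises IEEE negative zero
}

split_codons <- function(row) {
  n <- nchar(row)
  if (n %% 3L != 0L) stop("codon row length not divisible by 3")
  substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) pairwise dN/dS from a codon alignment
#'
#' Counts expected synonymous (S) and nonsynonymous (N) sites averaged
#' over the two sequences, observed synonymous (Sd) and nonsynonymous
#' (Nd) differences with multi-position codon differences averaged over
#' all mutational pathways (pathways through stop codons excluded when an
#' alternative exists), and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to the proportions `pS = Sd/S` and
#' `pN = Nd/N`. Columns containing a gap, an ambiguous base or a stop
#' codon are excluded.
#'
#' @param codon_aln A codon alignment from [thread_codons()]: list with
#'   `rows`, two gapped codon strings of equal length.
#' @return Object of class `"dnds_estimate"`: list with `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega` (`NA` when undefined),
#'   `n_codons` (usable columns) and `n_diff` (columns that differ).
#' @export
ng86_dnds <- function(codon_aln) {
  r1 <- split_codons(codon_aln$rows[1L])
  r2 <- split_codons(codon_aln$rows[2L])
  if (length(r1) != length(r2)) stop("codon rows differ in length")
  clean <- grepl("^[ACGT]{3}$", r1) & grepl("^[ACGT]{3}$", r2) &
    !(r1 %in% STOP_CODONS) & !(r2 %in% STOP_CODONS)
  r1 <- r1[clean]; r2 <- r2[clean]
  if (!length(r1)) stop("no usable (ungapped, unambiguous) codon columns")
  sites <- ng86_site_table()
  S <- (sum(sites[r1]) + sum(sites[r2])) / 2
  N <- 3 * length(r1) - S
  diffs <- vapply(seq_along(r1), function(i) ng86_pair_diffs(r1[i], r2[i]),
                  numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = length(r1), n_diff = sum(r1 != r2)),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf(
    "<dnds_estimate> %d codons (%d differing)\n  S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n  dS=%s dN=%s omega=%s\n",
    x$n_codons, x$n_diff, x$S, x$N, x$Sd, x$Nd,
    formatC(x$dS), formatC(x$dN),
    if (is.na(x$omega)) "undefined" else formatC(x$omega, digits = 4)))
  invisible(x)
}

#' Summarise selection over a set of dN/dS estimates
#'
#' @param estimates List of `"dnds_estimate"` objects.
#' @return List with `n_defined` (finite omega), `n_purifying`
#'   (omega < 1, strict), `fraction_purifying` (formatted via
#'   [format_percent()]; `NA` when nothing is defined) and `median_omega`
#'   (midpoint of the central pair for even counts; `NA` when nothing is
#'   defined).
#' @export
dnds_summary <- function(estimates) {
  om <- vapply(estimates, function(e) e$omega, numeric(1))
  om <- om[is.finite(om)]
  n_def <- length(om)
  n_pur <- sum(om < 1)
  list(n_defined = n_def, n_purifying = n_pur,
       fraction_purifying = if (n_def > 0)
         format_percent(n_pur, n_def)$percent else NA_character_,
       median_omega = if (n_def > 0) median(om) else NA_real_)
}

#' Simulate codon-level sequence divergence under selection
#'
#' Proposes substitutions uniformly over sites at expected rate `t`
#' substitutions per site; synonymous proposals are always accepted,
#' nonsynonymous proposals with probability `omega_true`, and proposals
#' creating a stop codon are rejected. Deterministic under `seed`.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stops.
#' @param t Expected proposed substitutions per site.
#' @param omega_true Acceptance probability for nonsynonymous proposals.
#' @param seed Integer seed.
#' @return The diverged coding sequence.
#' @export
simulate_codon_divergence <- function(cds, t, omega_true, seed) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cds length not divisible by 3")
  with_seed(seed, {
    chars <- strsplit(cds, "", fixed = TRUE)[[1]]
    n_prop <- rpois(1L, t * n)
    if (n_prop > 0L) for (i in seq_len(n_prop)) {
      site <- sample.int(n, 1L)
      alt <- sample(setdiff(BASES, chars[site]), 1L)
      cstart <- 3L * ((site - 1L) %/% 3L) + 1L
      old_cod <- paste(chars[cstart:(cstart + 2L)], collapse = "")
      new <- chars; new[site] <- alt
      new_cod <- paste(new[cstart:(cstart + 2L)], collapse = "")
      if (new_cod %in% STOP_CODONS) next
      if (codon_aa(new_cod) == codon_aa(old_cod) ||
          runif(1L) < omega_true) chars <- new
    }
    paste(chars, collapse = "")
  })
}
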