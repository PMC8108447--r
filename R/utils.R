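#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rgeom rnorm rpois runif setNames
#' @importFrom utils head read.delim tail write.table
NULL

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Reverse complement of a nucleotide string
#'
#' @param x A character scalar over the DNA alphabet.
#' @return The reverse complement, uppercase.
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# Vectorised random DNA with a mild GC bias (background GC ~ 0.45).
random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Integer sampled uniformly from an inclusive range given as c(lo, hi) or
# scalar. Degenerate ranges short-circuit (sample() would misread a scalar).
sample_range <- function(r) {
  if (length(r) == 1L || r[1] == r[2]) return(as.integer(r[1]))
  as.integer(sample(seq.int(r[1], r[2]), 1L))
}

stopifnot_scalar_chrom <- function(chrom) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
}
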