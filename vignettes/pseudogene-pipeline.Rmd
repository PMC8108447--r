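---
title: "Classifying and analysing processed pseudogene transcripts"
author: "pseudotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and analysing processed pseudogene transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotx)
```

## The problem

Processed pseudogenes arise when a spliced, polyadenylated mRNA is
reverse-transcribed and reinserted into the genome. Because their
sequence is nearly identical to the parent mRNA, short reads cannot
reliably tell a pseudogene transcript from parental transcription, and
reference annotations mark most pseudogenes as silent. Full-length cDNA
(long-read) transcript models change this: each model is an explicit exon
chain with a read-support count, so a pseudogene transcript can be
recognised by *where* it lies rather than by sequence alone.

`pseudotx` takes transcript models, a reference annotation with biotypes,
a retrocopy track, CAGE peaks/signal and the genome, and produces a
per-transcript classification plus cohort-level summaries. A synthetic
cohort generator with a truth manifest backs every stage with recovery
tests, so the pipeline is verifiable without any external download.

## Coordinates and containers

All internal coordinates are 0-based half-open (the BED convention); GTF
input and output are shifted at the boundary. Interval algebra is
strand-blind and backed by IRanges; orientation enters only through the
classifier. A transcript is an exon chain on one chromosome strand with a
full-length read count; a pseudogene record ties the pseudogene gene
model to its parent gene and the retrocopy interval, whose annotated
strand encodes the parent-mRNA orientation at the insertion site.

## The classification model

A transcript participates only if supported by at least `min_fl = 2`
full-length reads — single-read models are too often artefacts of
incomplete reverse transcription. It is then assigned to the gene model
with the greatest exonic overlap in bases against the gene's merged exon
union. Exonic base overlap (not overlap fraction, not junction identity)
is used because it is deterministic and robust to partial 3'/5'
truncation; ties prefer a pseudogene biotype and then the smallest gene
id, so re-runs are reproducible.

Assignment to a pseudogene is confirmed against a retrocopy track
(at least one exonic base over the retrocopy interval), which separates
transcripts of the reinserted copy itself from transcripts that merely
touch an annotated "transcribed pseudogene" exon elsewhere in the locus.

*Independence* requires two clauses: (i) the exonic overlap with the
pseudogene strictly exceeds the overlap with every non-pseudogene gene
model, and (ii) the transcript is not intronic (zero exon overlap while
inside the gene span) within any non-pseudogene gene. Clause (ii) is what
removes pseudogenes transcribed only as passengers of a host gene's
pre-mRNA. Other pseudogenes never count against independence.

*Orientation* compares the transcript strand with the retrocopy strand.
We deliberately do not consult the parent gene's chromosome strand: the
retrocopy's annotated strand already captures the parent-mRNA
orientation, and the parent may sit on another chromosome entirely.
Antisense transcripts flow through the same independence rule; nothing in
the rule references orientation, so the two calls stay orthogonal.

Splice-junction sharing with the reference uses exact
(chromosome, donor, acceptor, strand) identity. Mono-exonic transcripts
share nothing by definition.

## Evidence features

**PolyA motif.** The scan window is *genomic* (not spliced): the 100
bases ending at, and including, the 3'-terminal base, read in transcript
orientation. The canonical signal sits 10–40 nt upstream of the cleavage
site, so the window is searched on the upstream side; the window size is
a parameter. AATAAA takes precedence over ATTAAA when both occur, and
among occurrences of one motif the closest to the 3' end is reported,
with the offset measured from the terminus to the motif's last base.

**CAGE.** A TSS is supported when its distance to the nearest CAGE peak
is at most 100 bp, boundary inclusive; distance inside a peak is zero.
The meta-profile averages per-base signal in ±500 bp windows, reverses
minus-strand windows so profiles are 5'→3', and reports per-bin means so
cohorts of different sizes are comparable.

## ORFs, parental fraction, fusions

An ORF is the longest ATG-initiated, stop-terminated frame on the
transcript strand; a stop is required, so 3'-truncated models are not
credited with open-ended ORFs. Coding potential uses a strict
`> 100` amino-acid threshold. The "fraction of the parental ORF intact"
is a pure length ratio — pseudogene ORF length over the annotation's CDS
length (in amino acids) — capped at 1. An alignment-based intactness
score was considered and rejected: the quantity of interest is how much
of the parent's coding span survives frame disruption, which a length
ratio captures directly and deterministically.

Fusion transcripts (a protein-coding host transcript that splices in
pseudogene-derived sequence) are detected by combining the host
assignment with a ≥1 bp retrocopy overlap; each ORF codon is mapped
through the exon chain to genomic positions and counted as
pseudogene-derived when at least two of its three bases fall inside the
retrocopy interval. Overlap and strand are assessed independently, so
codons contributed from the antisense strand of a pseudogene are counted
and labelled as such.

## Selection on pseudogene ORFs

For each independent sense transcript with an ORF and an orthologous
window from a second species, the pipeline:

1. locates the ortholog by splice-naive Smith–Waterman local alignment
   (match +2, mismatch −3, gap open −5, extend −2); a non-positive best
   score means "no ortholog";
2. requires the located cDNA length to be divisible by three before
   translating;
3. aligns the two proteins by Needleman–Wunsch with BLOSUM62 and affine
   gaps (open −11, extend −1; a gap of length L costs 11 + L, and end
   gaps are penalised);
4. threads the protein alignment back onto codons (gap columns become
   `---`; the threading refuses inputs whose translation disagrees with
   the alignment rows); and
5. estimates dN/dS by Nei–Gojobori (1986) counting: per-codon expected
   synonymous site fractions from the standard code (changes to stop
   codons count as nonsynonymous), sites averaged over the two sequences,
   observed differences averaged over all mutational pathways with
   stop-crossing pathways excluded when an alternative exists, and
   Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)` applied to both
   proportions. `omega = dN/dS` is undefined when `dS` is zero or either
   distance is saturated (`p >= 3/4`).

A maximum-likelihood codon-model estimator would be the field's other
standard choice; NG86 counting was chosen because it is exactly testable
against brute-force enumeration (site counts per codon, pathway averaging
over all orderings) and agrees closely with ML at the low divergences
relevant to primate comparisons. The summary layer treats any estimator
producing (dN, dS) interchangeably.

"Sufficient nucleotide diversity" is operationalised as: at least one
observed difference, `dS` defined, and `dS > 0`. Transcripts failing this
are reported with status `insufficient_diversity` and excluded from the
summary denominator; the summary reports the count and fraction of
defined estimates with `omega < 1` (strict) and their median (midpoint of
the central pair for even counts).

One estimator property worth knowing: pathway averaging can attribute a
small nonsynonymous count to a codon hit twice by synonymous
substitutions (for example Leu TTA → CTA → CTC, whose two direct
pathways include a Phe intermediate), so `dN` may be fractionally above
zero even when every realised substitution was synonymous. This is
inherent to NG86 counting, reproduced exactly by independent
implementations, and visible only at appreciable divergence.

## The simulator and what it does (not) emulate

`sim_config()` defaults describe the study conditions the pipeline is
designed for: 20 parent genes of 2–5 exons and 120–300 codons at ~45% GC;
young processed pseudogenes (1% neutral substitution divergence, rare
indels) with an 8–20 bp polyA tract; 30% of copies carrying a planted
single-base frameshift at a recorded CDS fraction; 20% antisense
transcription; 15% intronic insertion; one gene–pseudogene fusion; CAGE
peaks of width 20 with 10 bp centre jitter; geometric full-length read
counts with minimum 1 so the support filter has work to do; and planted
polyA motifs 10–40 bp upstream of each 3' end. Ortholog windows re-run
divergence from the ancestral insertion along a second branch — neutral
on non-coding sequence (8% substitutions, a rhesus-like distance) and
under a codon model with true `omega = 0.4` on the CDS — which gives the
selection stage a realistic two-species input without any genome
download. Fusion pseudogene copies receive substitutions but not indels
or frameshifts, since an observed fusion ORF implies a surviving reading
frame.

The human-lineage divergence on pseudogene copies is neutral while the
ortholog branch is selection-filtered, so pairwise omega estimates on
simulator output mix a short neutral branch with the selective branch and
sit slightly above the branch's true omega. The direct parameter-recovery
analysis therefore uses `simulate_codon_divergence()` alone, where the
true omega is unambiguous.

Deliberate non-realism: intergenic background is i.i.d. with mild GC
bias (no repeats, so every retrocopy has a unique placement and
alignment ambiguity is absent); promoters are positional only; no
sequencing-error model (the pipeline consumes transcript models, not
reads); a single chromosome. Recovery tests passing on this synthetic
cohort therefore demonstrate the correctness of the pipeline's logic and
arithmetic — not robustness to repeat-mediated mis-assignment or
alignment noise in real genomes.

The `disable_reinitiation` flag builds a stricter fixture for the
frameshift analysis: parent CDSs carry no internal Met codon, UTRs are
scrubbed of ATG, and each planted frameshift is followed by an immediate
in-frame stop. Under that fixture the recovered parental-ORF fraction is
bounded by the planted disruption point *exactly*; with re-initiation
allowed (the default), downstream ATGs can rescue part of the frame and
the bound holds only approximately.

## Numerical and formatting choices

Percentages are formatted with one decimal below 10% and as integers
otherwise, rounding half up — a presentation rule recovered from the
reporting style this pipeline mirrors; stored counts remain exact.
Subcellular enrichment uses raw qPCR cycle thresholds,
`2^(Ct_cyt − Ct_nuc)` for nuclear enrichment and its reciprocal for
cytoplasmic, so the two directions multiply to one. Count matrices are
transformed as plain `log2(cpm + 1)` with no between-sample
normalisation: trimmed-mean normalisation is an off-the-shelf step that
belongs to the expression toolchain, not to this package's contribution.

Alignment gap costs follow the convention of the backing library: a gap
of length L costs `opening + L × extension`. The exhaustive-search oracle
in the test suite mirrors the same convention, so scores are compared
like for like. Local-alignment tie-breaking between equal-scoring target
spans follows the aligner's traceback; scores are deterministic and ties
do not arise on simulator input.

## Problem sizes used by the test and acceptance suites

Recovery analyses run a 40-parent / 50-pseudogene cohort (~200 planted
transcripts) noise-free and at 1% divergence; the frameshift analysis
uses 200 pseudogenes for a tight binomial check of the planted fraction;
parameter recovery uses 300-codon sequences at proposal rate 0.3 over 50
replicate seeds per true omega. These sizes give stable statistics while
keeping a full run in the tens of seconds on one CPU.

## Limitations

* The classifier mirrors an overlap-based operational rule; a structural
  isoform classifier may assign edge cases differently (e.g. partial
  intron retention at a pseudogene boundary). Discordance candidates are
  visible in the output as pseudogene-assigned transcripts with small
  assignment margins.
* Orthology is caller-supplied: the package aligns a cDNA within a given
  window but does not search genomes for orthologous loci.
* NG86 with Jukes–Cantor correction underestimates rates at high
  divergence (`p` approaching 3/4 is reported undefined rather than
  extrapolated).
* The polyA scan covers the two canonical hexamers only; weaker variants
  are out of scope.
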