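---
title: "circkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circkit)
```

## The problem

Back-splicing joins a splice donor to an *upstream* acceptor on the same
transcript, producing a covalently closed circular RNA (circRNA) with
neither 5' cap nor poly(A) tail.  In RNA-seq data the only direct evidence
for such a molecule is a junction-spanning read: one whose two halves map
to the same chromosome in reversed genomic order.  circkit implements an
annotation-free discovery pipeline around that signal, quantifies how much
of each locus's output is circular, and provides the downstream analyses
used to decide whether candidate circles are artifacts (trans-splicing,
template switching, paralogs) and whether they have properties expected of
functional molecules (abundance, cell-type specificity, conservation,
translation, miRNA-sponge capacity).

## Discovery model

1. **Linear pre-filter.** Reads are deduplicated (identical sequences
   within a sample collapse to one representative, the PCR-duplicate
   model) and aligned full-length and contiguously to the genome, both
   orientations, allowing up to 2 substitutions.  Anything that maps is
   removed from discovery and retained for expression (FPKM) estimates.
   Mapping uses `Biostrings::matchPDict` with a three-band trusted-band
   scheme: the read is cut into three bands and matched three times, each
   run trusting one band; by pigeonhole every alignment with at most two
   mismatches has a clean band, so the union of the runs is exhaustive.

2. **Split alignment.** Each surviving read (and its reverse complement)
   is searched for two-part exact alignments: a 5' segment and a 3'
   segment, each at least `anchor_min = 20` nt, both matching the genome
   exactly, on the same chromosome, in reversed order, spanning at most
   100 kb.  Implementation: anchor the read's first and last 20-mer,
   extend each anchor maximally, and intersect the extension ranges; the
   quantity `segment position - breakpoint` is invariant under breakpoint
   sliding, so micro-homology at the junction collapses to a single
   placement with a recorded sliding range.  A read with more than one
   distinct placement is discarded as ambiguous (specificity over
   sensitivity).  A brute-force oracle -- enumerate every breakpoint and
   every occurrence of both segments -- verifies equivalence on random
   genomes in the test suite.

3. **Splice-signal refinement.** Within the sliding range (at most
   `shift_max = 5` either way, smallest |shift| first, ties toward
   negative), the junction is pinned to the shift whose flanks carry the
   major-spliceosome signal: on the forward genome `AG ] circle [ GT` for
   a plus-strand junction, `AC ] circle [ CT` for minus.  Strand is
   inferred from the signal orientation, the only reliable cue in
   libraries of mixed strandedness.  Failing GT-AG, the minor-spliceosome
   AT-AC signature is tried the same way; otherwise the candidate is
   classified `other` (and later excluded from the catalog, while still
   feeding the dinucleotide-enrichment diagnostic).  Junctions whose 10-nt
   flanking windows contain `N` are classified `other` -- the paper-style
   rules are silent on ambiguity codes and this is the conservative
   choice.

4. **Candidate calling.** Junctions need at least 2 distinct supporting
   reads within one sample.

## Quantification model

For each junction, the donor probe is the last 20 exonic nt ending at the
donor end and the acceptor probe the first 20 exonic nt from the acceptor
start (transcript orientation).  Reads are counted by exact substring
containment, both orientations, once per read:

* `n_donor`: contains the donor probe with at least 20 read nt remaining
  3' of it ("enough sequence space for the other sequence");
* `n_acceptor`: symmetric on the 5' side;
* `n_junction`: contains the 40-mer junction word, donor probe followed
  immediately by acceptor probe as read around the circle.

The circular fraction is `n_junction / (n_donor + n_acceptor - n_junction
+ 1)`.  Because a junction read contains both probes, `n_junction <=
min(n_donor, n_acceptor)` and the fraction lies in [0, 1).  The catalog
keeps GT-AG junctions with fraction >= 0.10 in >= 2 samples; a
high-fraction sublist flags junctions at >= 50% in most samples where the
transcript was detected.  Abundance is inferred as fraction x gene FPKM,
and the circRNA share of the transcriptome as fraction x FPKM x exonic
length summed over circles, normalized by FPKM x exonic length over
expressed (FPKM >= 0.1) protein-coding genes.

## The simulator: what it emulates, and what a green test establishes

`sim_genome()` builds random-sequence genes whose introns carry canonical
GT..AG signals on the annotated strand; `sim_truth()` plants back-splice
junctions on exon boundaries with a true circular fraction per sample;
`sim_reads()` draws ~200-nt fragments (Normal(200, 30), both 100-nt ends
reported) from a template pool; `sim_rpf()` draws ~30-nt
ribosome-footprint reads from spliced linear transcripts only.

Two design points matter for correctness of the recovery tests:

* **Tandem circular template.** A circle is represented as 3 tandem copies
  of its spliced sequence, so fragments can start anywhere, including
  across the back-spliced seam, without special-case logic.  A
  consequence used deliberately: the tandem template presents exactly 2
  seams per molecule while a linear molecule presents 1 donor + 1
  acceptor probe site, so with fragment mass proportional to molarity x
  template length the estimator above is *unbiased* for the molar
  circular fraction.  Template weights are therefore molarity x
  (length - mean fragment + 1), i.e. equal fragment-start density per
  nucleotide across isoforms.

* **Interior junction sites.** Fragments must fit inside a template, so a
  probe window within one fragment length of a transcript end loses mate
  coverage and the estimator acquires an edge bias.  Real mRNA termini
  behave the same way; the parameter-recovery property presupposes
  junction sites interior to the transcript, and the recovery worlds use
  terminal exons longer than a fragment (220-320 nt).

The simulator does *not* emulate sequencing-quality profiles, GC bias or
realistic isoform-abundance distributions (configurable substitution
errors default to 0, matching the exact-match split stage).  A green
recovery test therefore establishes correctness of the estimator and
filters under the stated sampling model, not robustness to real-library
artifacts.

Trans-splicing contaminants (`kind = "trans"` in `sim_truth()`) are
emitted as linear, polyadenylated exon-shuffled transcripts whose seam is
read-identical to the back-splice junction -- the positive control for the
two discrimination analyses: mates of junction-spanning reads mapping
strictly outside the junction span (a circle has no outside), and
persistence in a poly(A)-selected library (circles vanish there).

Intron retention is molecule-level: with probability `r` a circular
molecule keeps its internal introns.  The mate-based estimator (intron
mates / (intron + neighbor-exon mates)) recovers `r` without capture bias
when the boundary exons are shorter than a read and the internal introns
are longer than a fragment minus a read, so that spliced and retained
molecules offer equal capture for their informative mates; the test worlds
use 40-nt boundary exons with 200-nt introns accordingly.

## Characterization analyses

* **Cell-type specificity**: `1 - sqrt(JSD(p, e_t))` maximized over
  samples `t`, base-2 logarithms with `0 log 0 := 0` (bounded in [0, 1],
  1 exactly for single-sample profiles).  We maximize over samples, the
  standard form of the score.  The control cohort matches the circRNA
  set's distribution of total junction-spanning reads (counts, not FPKM)
  in unit-width `log2(total + 1)` bins, without replacement where
  possible; an empty bin falls back to the nearest populated bin with a
  warning.
* **Fraction matrix**: junctions with donor and acceptor availability >= 5
  reads in every sample; pairwise Spearman correlation across samples.
* **Conservation**: gene-level 2x2 ortholog enrichment; junction-level
  overlap classes after coordinate mapping (boundary tolerance +-2 nt for
  "same splice sites", absorbing cross-species mapping round-off);
  average circular fractions (over samples with >= 1 donor and acceptor
  read) compared by Spearman correlation; codon-position conservation of
  circular coding exons against the nearest upstream and downstream
  coding exons of the same transcript (paired two-sided Wilcoxon,
  normal approximation; p = 1 when all paired differences are zero), and
  a 1,000-cohort null matched on position-1&2 mean conservation
  (equal-width bins over the pooled range).
* **Translation**: 20-nt probes across the circular junction and its two
  annotated linear junctions (10 nt each side).  Eligibility requires RPF
  reads at both linear junctions.  The RNA-seq circular fraction uses the
  standard containment formula; the RPF fraction uses the probe-count
  analog circ/(donor+acceptor-circ+1), the only informative estimator for
  ~30-nt footprints (the containment rule needs 40 nt of read).  A probe
  is paralog-flagged when its 20-mer occurs contiguously in the genome or
  its half-words co-occur in linear splice order within 100 kb -- one
  defensible operationalization of the paralog exclusion, which the
  source methods do not specify.
* **miRNA sites**: canonical 8mer / 7mer-m8 / 7mer-A1 words from the seed
  (DNA space; U/T normalized on input), counted by exact scan with 8mer
  precedence so classes are disjoint.  Sites are not counted across the
  circular junction by default (`wrap_junction = TRUE` appends the first
  7 nt for circle-aware scanning).  Null cohorts replace each 8mer by a
  uniformly drawn permutation preserving mononucleotide composition, the
  CG-dinucleotide count (counted on the linear word) and the terminal A;
  the original word is excluded from the draw (a null that could redraw
  the site itself could never be exceeded), with a warned fallback for
  degenerate words like `AAAAAAAA`.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open on the forward strand;
  GTF (1-based inclusive) converts at the boundary.  BED12 blocks are
  used as-is.
* Shift tie-break in refinement: smallest |s|, ties toward negative
  (minimal perturbation of the observed alignment).
* Exon-model tie-break: among transcripts matching both junction
  boundaries, most exons inside the interval, then longest.
* Exons shorter than a probe truncate the probe with a warning; circles
  with no annotated transcript match fall back to a single-exon model.
* Mann-Whitney / Wilcoxon tests use the normal approximation
  (`exact = FALSE`) for predictable behavior with ties; the degenerate
  all-zero-differences case is reported as p = 1.
* Statistical calibration of the codon-position and cluster-density
  tests is verified at the 5% level over 1,000 simulated null
  replicates in the acceptance suite.

## Known limitations

* The mate analyses count only contiguously mapping mates; mates spanning
  linear splice junctions are dropped, which loses information when
  boundary exons are much shorter than the read.
* Discovery uses individual reads only (single-end logic); mates enter
  downstream analyses but not junction calling.
* The trans-splicing mate test is restricted to circles shorter than
  400 nt, a consequence of the ~200-nt fragment size; for longer circles
  the poly(A) comparison is the informative discriminator.
* FPKM assigns fragments by contiguous genomic overlap with the gene's
  exon union; fragments spanning splice junctions are not counted,
  an undercount shared by all genes in a comparison.
* The catalog filter's >= 10% threshold is a hard boundary: a junction
  whose true fraction sits exactly at 0.10 is retained in roughly half of
  samples by sampling noise alone.
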