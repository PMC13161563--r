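---
title: "Methods: designing and characterizing CAG-repeat-targeting artificial miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and characterizing CAG-repeat-targeting artificial miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagmir)
```

## The problem

Polyglutamine diseases (Huntington's disease, several spinocerebellar
ataxias, DRPLA) are caused by expanded CAG repeats in the coding region of
otherwise unrelated genes. A repeat-directed silencing strategy targets the
CAG tract itself with a CUG-repeat-like guide strand: on the long mutant
tract many silencing complexes can bind cooperatively, while the short
normal tract binds few, which is the basis of allele selectivity.
Deliberate internal mismatches (an A:A mismatch at guide position 8 in the
parental A2 design, plus one additional substitution in its derivatives)
switch the mechanism from transcript cleavage to a miRNA-like
translation-inhibition mode and, critically, reduce complementarity to
CAG-rich off-target sequences elsewhere in the transcriptome.

cagmir implements the computational workflow around such a molecule:

1. **Guide design** — substitution variants of a parental guide and their
   mismatch profiles against repeat targets (`apply_substitution()`,
   `mismatch_profile()`, `substitution_scan()`).
2. **Off-target scanning** — exhaustive Hamming-budget enumeration of
   binding sites over genome/transcriptome FASTA, locus merging, region
   annotation, per-variant summaries and ranking.
3. **Processing QC** — classification of small-RNA-seq reads against the
   amiRNA hairpin into arm and 5′-start-site (isomiR) groups, strand bias,
   length distribution, and abundance relative to endogenous miRNAs.
4. **Restoration statistics** — concordance of log2 fold changes between
   treated-vs-healthy and untreated-vs-healthy differential-expression
   comparisons.
5. **Synthetic data** — seeded generators with exact truth tables for all
   of the above, so every stage is testable at desk scale.

## Mismatch profiles and registers

A guide is written 5′→3′ in RNA; positions are 1-based from the 5′ end. The
guide faces the repeat tract antiparallel, so it is compared base-by-base
with the phased repeat complement — for a CAG target, the (CUG)ₙ reference,
with frame 0 starting at C. Pairing is strict Watson–Crick (A–U, G–C only):
G:U wobble is deliberately counted as a mismatch because off-target
counting operates in DNA space, where an alignment has no wobble. The
parental A2 guide differs from the pure CUG reference only at position 8;
each designed variant adds one substitution, so its frame-0 profile is
{8, p}:

```{r profiles}
mismatch_profile(a2_guide(), repeat_target(28), frame = 0)
mismatch_profile(designed_guides()$`13A`, repeat_target(28), frame = 0)
```

The *best frame* of a sequence is the frame minimizing the mismatch count,
with ties broken by the lowest frame index. Ties only arise for sequences
far from the repeat, where any choice is equally (un)informative, so the
deterministic low-index rule is used. A 5′ extension by one perfectly
pairing base shifts every profile position by +1 — this register-shift
property is why a +1-shifted 5′ isomiR of the 13A guide carries mismatches
at {9, 14} instead of {8, 13}:

```{r shift}
mismatch_profile("GCUGCUGCAGCUGAUGCUGC", repeat_target(28))
```

Longer tracts expose more in-frame binding registers (one per added repeat
unit once the tract covers the guide), quantifying the substrate for
cooperative binding:

```{r registers}
vapply(c(16, 57, 85), function(n)
    inframe_register_count(repeat_target(n), 19, 2), 0L)
```

## Off-target scanning

A guide's *target site* is its DNA reverse complement — the sequence a
complementary transcript or genomic window would carry. `scan_offtargets()`
reports every window of the database whose Hamming distance to the site is
at most the budget (0–3), with no indels, mirroring ungapped short-query
alignment. Genome scans run in both-strand mode; transcriptome scans run
sense-only, because the guide binds mRNA.

The production path uses pigeonhole seeding, implemented in C++: with
budget *k* the site is split into *k*+1 near-equal segments, at least one
of which must match exactly in any window within budget; exact segment
matches anchor candidate windows, which are then fully verified. A naive
vectorized sliding-window scan (`method = "naive"`) is retained as an
independent route; the contract is the hit set, not the algorithm, and the
test suite asserts identity of the two hit sets against a third,
byte-level oracle. Windows containing ambiguous bases (N) are excluded
rather than treated as wildcards, and tallied.

Counts are reported in *exact* mismatch bins (a transcript whose best site
has one mismatch counts at k = 1 only); cumulative counts are derivable
downstream. Because published genome-level counts do not say whether
near-match totals are windows or merged loci, both levels are available
(`level = "window"`, `"locus"`), with `merge_loci()` unioning windows on
the same sequence and strand that overlap by at least 1 bp (book-ended
windows stay separate). Region annotation labels a locus with every region
type it overlaps by ≥ 1 bp, falling back to `intergenic`. Variant ranking
is ascending lexicographic on (k0, k1, k2, k3) with alphabetical
tie-breaks, which formalizes "fewest fully complementary sites first, then
fewest near-complementary".

Coordinates are 0-based half-open internally and in BED output; 1-based
only in human-readable text.

## Hairpin processing of small-RNA reads

Reads (adapter-trimmed, 15–30 nt by default) are matched to the hairpin by
their longest exactly matching prefix; up to 2 trailing non-templated
nucleotides are tolerated. Exact matching is appropriate because coverage
of a short hairpin is deep and sequencing-error reads can safely fall to
`unassigned` (never silently dropped; conservation `assigned + unassigned
= total` is asserted). The repeat-rich insert can make a read match at
several offsets; ties are broken by the leftmost offset within an
annotated arm (expanded by the 5-nt start slack), then leftmost overall,
and the ambiguity is tallied.

Groups are formed per (arm, 5′ start offset); groups under 0.5% of
assigned reads are pooled into a per-arm "other" group. Strand bias is the
guide/passenger percentage split over assigned reads; templated lengths
give the length histogram; each guide group's representative sequence is
profiled against the repeat target at its best frame, attaching register
mismatches ({8,13} for the canonical start, {9,14} for the +1 isomiR).
Counts are the internal currency; percentages are computed only at report
time. Abundance relative to the endogenous pool is reported both as the
percentage of the summed top-N (default 50) endogenous mature miRNAs and
of all supplied miRNAs, since either denominator is defensible.

The synthetic hairpin (`amir13a_hairpin()`) is a labelled synthetic
stand-in, not a published scaffold sequence: the 13A guide on the 5′ arm,
its reverse complement as the 3′ passenger arm, and arbitrary non-repeat
flanks and loop. The base immediately 5′ of the guide arm is a G that
pairs perfectly in the repeat register, fixing the +1-isomiR worked
example; with real data the flanking bases come from the hairpin
configuration file.

## Restoration statistics

Given DESeq2-style tables for treated-vs-reference and
untreated-vs-reference, `restoration()` intersects genes significant in
both (default criterion `padj < 0.05`; `pvalue` is available as a flag
because published "P < .05" captions are ambiguous), computes the Pearson
correlation of the paired log2 fold changes via `stats::cor.test()`, and
counts sign reversals. Genes with a fold change of exactly 0 are neither
concordant nor reversed and are tallied separately; genes with missing
effect or significance values are dropped with a tally. The statistic is
symmetric in its two tables and invariant to positive rescaling of either
effect vector. With fewer than 3 shared genes or zero-variance effects,
r is flagged undefined rather than reported. No fold-change filter is
applied by default.

## Synthetic data and what passing tests show

Every generator is a pure function of `(seed, parameters)` and emits a
truth table sufficient for scoring.

* `make_genome()` plants target sites with an exact number of mismatched
  positions (drawn uniformly without replacement, each base changed) on
  random strands, plus repeat tracts, over a random background. The
  background is rejection-checked with the naive oracle to contain no
  window within the scan budget of any planted site, and the assembled
  sequence is re-verified so that any in-budget window overlaps a planted
  span. Repeat-like sites necessarily produce shifted near-budget windows
  over the plant itself, so exactness means "clean background", and
  precision is defined as every reported hit verifying to its stated
  distance.
* `make_reads()` draws reads multinomially from a variant mixture whose
  defaults mirror the measured processing composition (guide +1 isomiR
  35.9%, canonical guide 32.4%, other guide starts 17.2%, passenger 14.5%,
  i.e. 85.5% guide-arm reads), with templated 3′ extension probabilities
  spanning lengths 19–23 nt and non-templated 1–2-nt tails at rate 0.15
  whose first base is chosen to differ from the next hairpin base. The
  endogenous background is a log-normal count table (150 species,
  meanlog 8, sdlog 1.5) — values chosen once as a plausible small-RNA
  library shape. Depths below 1000 set a wide-tolerance flag.
* `make_de_tables()` plants a co-significant gene set with bivariate-normal
  effects at the target correlation and sub-alpha adjusted p-values;
  remaining genes are significant in at most one table, so the shared set
  is exactly the planted one.

The generators emulate the *statistical* structure the contracts need —
planted distances, mixture proportions, correlations — not biological
realism: no genome-scale repeat landscape, no sequencing-error model
(constant FASTQ quality), no DE model fitting. Passing tests therefore
demonstrate the correctness of the computations, not pipeline thresholds
on any particular accession; reproducing published percentages from raw
accessions additionally depends on read-collapsing and mapping-tolerance
choices that are exposed as configuration.

## Numerical and testing choices

Desk-scale problem sizes keep the full suite under a minute of compute:
oracle-equivalence scanning uses 100 random sequences of 1–5 kb across
budgets 0–3 and both strand modes; planted-site recovery uses a 5-Mb
genome (10 × 500 kb, 24 planted sites at 0–2 mismatches); mixture recovery
uses 20 seeds at depth 10⁵ with three-sigma multinomial bounds (at most
one excursion expected across the 80 checks); restoration recovery uses
2000-gene tables with 111 planted co-significant genes, checked against
the Fisher-z 99% band, plus a 50-seed mean-recovery check at n = 200.
Statistical assertions use bounds derived from sampling theory, never
tuned constants.

## Limitations

* Hamming-only matching: no indels, no G:U wobble, no seed-region
  weighting or thermodynamic (ΔG) modelling — ranking is purely
  complementarity-count based, as in the design workflow it reproduces.
* No RISC-loading or silencing-efficacy prediction; allele selectivity is
  established experimentally, not modelled.
* Read classification assumes adapter-trimmed input and exact hairpin
  matches; heavily error-laden libraries will inflate `unassigned`.
* DE tables are consumed as produced upstream; no model fitting,
  normalization, enrichment or PCA.
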