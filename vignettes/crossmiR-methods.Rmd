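---
title: "Cross-species miRNA discovery: models, parameters and design choices"
author: "crossmiR"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Cross-species miRNA discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plant species without an assembled genome cannot use the standard miRNA
discovery recipe, which requires folding the genomic neighbourhood of every
mapped small-RNA read to test for a hairpin precursor.  crossmiR implements
the cross-species workaround: reads are mapped to the genome of a close
relative (the *surrogate* reference), hairpins are validated there, and
conserved miRNAs that the surrogate misses (through sequence divergence)
are rescued by direct homology to a known-miRNA catalogue.  Differential
abundance between libraries is then assessed with the Audic–Claverie exact
test for digital expression counts.

This vignette records the models behind each stage, the tunable parameters
with their defaults, the behaviour of the synthetic-data generator used by
the test suite, and the places where the design was genuinely open together
with the choice we made.

# Pre-processing

Reads are quality-floored (every base at or above Phred 20, FASTQ only),
adapter-trimmed, length-filtered and collapsed to unique counted tags.

* **Adapter** (`adapter`, default `ATCTCGTATGCCGTCTTCTGCTTG`): the 3'
  sequencing adapter.  Trimming takes the leftmost full internal match or
  the longest adapter *prefix* anchored at the read's 3' end with at least
  `minOverlap` (default 6) bases.  Reads with no detectable adapter are
  discarded: without the adapter boundary the insert length is unknown,
  and an sRNA tag's identity *is* its exact sequence.
* **Length window** (`minLen`/`maxLen`, 18–26 nt): the plant sRNA size
  range produced by the DCL enzymes; shorter fragments are degradation
  products, longer ones are not Dicer products.
* **ncRNA filter**: a tag is removed when it is an exact substring of any
  rRNA/tRNA/snRNA/snoRNA reference or its reverse complement.  Exact
  matching (no mismatch tolerance) is deliberate: it is deterministic,
  conservative, and the reference sets are from the same or a close
  species.
* **Masking**: tags whose most frequent nucleotide exceeds 80% of
  positions (strictly), or that are pure 1–2 nt repeats, are dropped as
  low-complexity.  This is a sequence-intrinsic rule; we do not mask
  against genomic repeat annotations.

Every stage is accounted: reads in = reads out + reads removed, per
sample, and the stage report reproduces that accounting.

# Mapping to the surrogate genome

Tags are placed by perfect, full-length, both-strand matches using a
16-mer seed index with full verification, so the index reproduces a naive
scan exactly (a tested invariant).  Tags hitting more than `maxLoci`
(default 10) genomic positions are discarded as repeat-derived; tags with
no hit are routed to the homology-rescue path.  The threshold follows the
"discard above ten loci" reading; the alternative "strictly fewer than
ten" is one configuration value away.  At each distinct 5' genomic
position the highest-count tag represents the locus (ties: longer tag,
then lexicographically smaller), matching the idea that the modal Dicer
product defines the mature species.

# Hairpin discovery

For each representative tag with more than `minCopies` (default 25) reads
the genomic window tag ± `windowMargin` (default 500 bp) is extracted in
transcription orientation and folded.

## The baseline folding engine

The default engine maximises total base-pair weight (GC = 3, AU = 2,
GU = 1) over non-crossing pairings with a minimum hairpin loop of 3 nt —
a weighted Nussinov scheme.  Its traceback is fully specified: the
leftmost base pairs the largest partner attaining the optimum, otherwise
it is left unpaired, so bifurcations occur at the smallest split point.
Two properties motivate this engine: it is deterministic across platforms
with no thermodynamic parameter tables, and it is simple enough to verify
against an independent dynamic-programming recursion and exhaustive
enumeration (both in the test suite).  A thermodynamic engine (ViennaRNA's
RNAfold, when the binary is on the PATH) can be plugged in via
`foldingEngine("vienna")`; with a thermodynamic engine an additional
stability gate applies (energy per nucleotide at or below −0.2 units).

A weight-maximising folder has a known pathology on long windows: almost
every base can pair *somewhere*, so the global optimum need not contain
the local hairpin, and at duplex ends random flanking bases can substitute
for end pairs at equal weight.  Two design decisions compensate:

1. **Multi-scale star search** (`locate_star`): the 500 bp window is
   folded first, matching the protocol order; if the mature arm does not
   pair into a consistent local stem, the search refolds at precursor
   scale (±150, ±80 nt) and finally scans the window directly for the
   best reverse-complement partner region.  Every candidate star is
   validated the same way (below) before acceptance.
2. **Arm-segment validation**: duplex statistics are computed on a fold of
   the excised mature..star segment.  The reported precursor is that
   segment extended by `refoldMargin` (default 15 nt) on each side and
   refolded — the published trim-and-refold step — but its random margins
   are excluded from duplex scoring, removing the end-pair degeneracy.

## Star location and duplex statistics

From a folded structure the star arm is inferred from the longest
"helix-like" run of mature positions: partners strictly decreasing, with
partner spacing tracking mature spacing within a 3 nt bulge tolerance.
At least half the mature bases must pair outside the mature interval,
otherwise the mature lies in a loop and the locus is rejected.  The star
interval endpoints are projected from the run extremes under the 2-nt 3'
overhang register of Dicer products (mature position 1 pairs star end −2;
mature position L−2 pairs the star start), which stays exact in the
presence of one asymmetric bulge.

The duplex report counts: *mismatches* (mature positions unpaired whose
projected star counterpart is also unpaired), the *largest asymmetric
bulge* (maximum difference of opposing unpaired runs between consecutive
paired positions), and the 3' *overhangs* (distance from each arm's 3'
end to its last base pairing into the other arm).

## Acceptance criteria for a candidate

A candidate is accepted when all of the following hold (each threshold
configurable):

* mature length 18–26 nt;
* duplex mismatches ≤ 4 (`duplexMaxMismatch`);
* largest asymmetric bulge ≤ 2 nt (`maxBulge`);
* both arms on one stem: into-star partners monotone, at least half the
  mature pairing there;
* each 3' overhang within 1..3 nt (`overhangRange`; the canonical value
  is 2, the tolerance absorbs end breathing);
* read signature: the mature tag has **more than** 25 copies
  (`minCopies`, strict), and at least `minConsistency` (default 0.75) of
  the locus reads start within ±2 nt of the mature or star 5' end.

The signature filter replaces a probabilistic biogenesis score with a
deterministic read-stack consistency measure: genuine Dicer products
stack at duplex ends, while degradation fragments start anywhere.  Loop
reads count as inconsistent.  The read set scored is the reads whose 5'
ends fall inside the trimmed precursor span — not the full ±500 bp window
— because a 1 kb window routinely contains unrelated neighbouring loci
whose reads would dominate the denominator.

Overlapping accepted precursors on one strand are merged keeping the
highest-count mature, so a locus is reported once even when both the
mature and its star pass the copy gate.

# Homology annotation and families

Candidate matures are compared to a known-miRNA catalogue by ungapped
alignment over terminal shifts of at most `homologyMaxShift` (default 2)
nt, tolerating `homologyMaxMM` (default 2) mismatches — the common
practice for catalogue matching; gaps are not allowed.  Matches become
*conserved*, the rest *novel*.  Unmapped tags with a catalogue match are
rescued as conserved (the cross-species mapping misses diverged loci);
unmapped tags without one leave the miRNA set.  Conserved members inherit
the catalogue family (parsed from names like `miR156a`); novel matures are
single-linkage clustered at ≤ 2 mismatches and named `Ng1`, `Ng2`, … in
descending total count so the numbering is deterministic.

# Target prediction

A miRNA–mRNA duplex is scored additively, position by position from the
miRNA 5' end, antiparallel to the transcript window: Watson–Crick pair 0,
G:U wobble 0.5, mismatch 1, gap 1 per gapped position, all doubled in the
core (miRNA positions 2–13) where plant targeting is least tolerant.
Scanning evaluates every ungapped window plus all alignments with one
single-nucleotide bulge on either strand; one bulge keeps the dynamic
programme trivial and matches the 0.5-step granularity of published
penalty scores.  Non-overlapping sites at or below `targetReportCutoff`
(default 7) are reported in ascending penalty; sites at or below
`validationCutoff` (default 4, inclusive — "four or less") are
validation grade.  The predicted cleavage coordinate is the transcript
base paired to miRNA position 10, i.e. slicing between the bases opposite
miRNA nucleotides 10 and 11, the canonical plant AGO register; with a
bulged alignment the coordinate walks the alignment rather than using
window arithmetic.  Only the transcript sense strand is scanned: the
inputs are oriented mRNA contigs.

# Differential abundance

For a tag with `x` counts in a library of `N1` total tags, the probability
of seeing `y` counts in a library of `N2` is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}$$

computed in log space via `lgamma`.  The two-sided p-value doubles the
smaller tail (both tails including the observed point), capped at 1.  The
test is scale-invariant in the totals (a tested invariant) and matches
direct tail summation to 10 significant digits.  Tail doubling makes the
test slightly conservative — its measured size at alpha 0.05 is about
0.047–0.050 over a wide count range (a property test pins this at 20,000
null draws) — which is the standard trade-off for an exact two-sided test.

Enrichment calls default to *one-vs-rest*: sample *s* is enriched for a
tag when the p-value of (pooled-rest count, sample count) falls below
`alpha` (default 0.001, the published threshold) **and** the normalised
rate in *s* exceeds the pooled rate.  A *pairwise-any* mode is provided
because some published per-cultivar calls are only explicable pairwise.
Normalisation totals default to the per-sample sum of all clean-tag
reads, with an explicit override (used when reproducing published
numbers, whose totals are the printed 18–26 nt library sizes).  No
multiple-testing correction is applied, matching the original protocol; a
Benjamini–Hochberg column is emitted for information only.

# The synthetic-data generator

The generator exists so that every stage is testable without downloads,
with machine-readable ground truth.  Defaults emulate the study
conditions at desk scale:

* 100 kb genome at GC 0.40 with 20 planted hairpins on random strands,
  ≥ 100 bp apart;
* mature lengths 20–22 nt (dominant 21) with a 5' U bias (65% U / 12% A),
  half drawn from a simulated catalogue (minimum pairwise Hamming
  distance 5) to model conserved miRNAs, half invented at > 2 mismatches
  from every catalogue entry;
* planted duplexes with 0–3 mismatches and 0–1 nt asymmetric bulges,
  loops of 15–40 nt, 2-nt 3' overhangs by construction;
* log-normal mature abundances (meanlog = log 300, sdlog = 1) floored at
  50 reads — heavy tails as real miRNA families show; star reads at 10%
  of mature (stars are degraded in vivo; the ratio is configurable);
* 5' jitter probability 0.1 (±1–2 nt), uniform-quality 36-nt reads =
  insert + adapter truncated; background genome fragments (18–26 nt, with
  a 21/24 bias) and ncRNA fragments as contamination;
* four samples of 20,000 reads each by default — large enough for stable
  recovery statistics, small enough that the full pipeline runs in tens
  of seconds per sample.

Two generator behaviours deserve emphasis.  First, *boundary control*:
loop ends, star overhangs and bulge bases are drawn from bases that
cannot pair their facing duplex ends, so the baseline folder reproduces
the planted register rather than an equal-weight shifted one.  Second,
*fold-back verification*: a draw is accepted only if folding the emitted
precursor recovers the planted star interval and duplex statistics
(mismatches within the planted count, bulge exactly as planted); draws
where an alternative structure wins are redrawn, with a generation error
after bounded retries.  Both are part of the generator's contract that
emitted truth records are consistent with the emitted sequences.

What the generator does **not** emulate: sequencing errors beyond uniform
quality, polymorphism, RNA degradation gradients, expression-dependent
ligation bias, and genomic repeat structure.  Passing the planted-recovery
tests therefore demonstrates the pipeline's logic, not its performance on
real libraries, where these factors reduce sensitivity.

# Numerical and procedural choices

* Internal alphabet is DNA (T); mature sequences are reported as RNA (U).
  Coordinates are 0-based half-open internally; GFF3/TSV outputs are
  1-based inclusive.
* All randomness flows through per-call seeds (`with_seed`), so repeated
  runs are byte-identical; the run manifest contains no wall-clock fields
  for the same reason.
* Test problem sizes: unit tests use 15–20 kb genomes with 4–5 hairpins;
  the end-to-end recovery experiment uses the full default simulation
  (100 kb / 20 hairpins, one sample).  The folding DP is O(n³) in C++
  (~0.4 s for a 1 kb window), which sets the per-locus cost.
* Degenerate inputs: empty tag sets yield empty results at every stage;
  empty catalogue or missing required inputs raise configuration errors
  before any computation.

# Known limitations

* The baseline engine's weight maximisation is not a free-energy model;
  candidate ranking by `energy` is only meaningful within an engine.
* Homology rescue cannot distinguish a diverged conserved miRNA from a
  degradation fragment that happens to match the catalogue within 2
  mismatches; rescued tags carry no structural evidence by definition.
* One bulge per target site bounds the alignment search; longer
  asymmetric loops found by full Smith–Waterman-style scoring are missed.
* With two samples the one-vs-rest and pairwise-any enrichment modes
  coincide; with more samples one-vs-rest pools heterogeneous libraries
  into one background, which can mask sample-specific enrichment.
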