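---
title: "Consensus gap filling: methods and design"
author: "gapmend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gap filling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmend)
```

## The problem

Chromosome-level assemblies built from one read type routinely retain
N-gaps — runs of unknown sequence where the assembler could not bridge a
repeat or a coverage hole. When a second assembly of the same species (for
example, from a different individual or a different long-read technology)
happens to be contiguous across those loci, its sequence can be spliced
into the gaps, producing a *consensus* assembly that is gap-free even
though neither input was. gapmend implements this reconciliation step:
given a gapped target assembly, a donor assembly and whole-genome
alignments between them, it plans and applies one patch per gap, then
validates and annotates the result.

The package deliberately does *not* run an aligner, polisher or
scaffolder; it consumes alignments in PAF or MUMmer `show-coords -rTH`
form and emits standard formats (FASTA, AGP, BED, TSV, JSON) so it can
slot between the usual tools.

## The patching model

A **gap** is a maximal run of `N`/`n` of length at least `minGapLen`
(default 1, exposed as a flag: assemblies differ in what they record as a
gap, and counting every run is the conservative choice). All coordinates
are 0-based and half-open internally; BED shares that convention and AGP
conversion happens only at serialization.

For each gap the planner looks for **anchors** — filtered alignments that
reach within `flankWindow` (default 5 kb) of a gap edge on the correct
side with a block length of at least `minAnchorLen` (default 1 kb). Three
cases arise:

1. **Spanning**: one alignment covers the whole gap. The gap edges are
   projected through the alignment's coordinate map and the projected
   donor interval becomes the patch. Spanning alignments are always
   preferred: they assert donor contiguity across the locus directly.
2. **Paired**: a left and a right anchor on the same donor contig, same
   strand, donor-colinear. Among concordant pairs the one with the
   highest summed alignment score wins; ties go to the smaller donor span
   and then the lexicographically smaller donor name, so planning is
   deterministic.
3. **Failure**: every other situation becomes a status
   (`no_left_anchor`, `no_right_anchor`, `discordant_anchors`,
   `span_too_long`, `donor_overlap_unresolvable`) rather than an error —
   a per-gap audit trail mirrors how a curator would review each locus.

Coordinate projection is linear interpolation between alignment
endpoints. The coords dialect carries no CIGAR, so base-level projection
is impossible by construction; interpolation is exact for colinear
(substitution-only) divergence and its error is bounded by the indel
content of the alignment, which junction validation catches downstream.
When an anchor stops short of the gap edge the projection extrapolates
linearly past the alignment end rather than trimming target flanks — the
flank bases are observed sequence and are kept unless the donor
actively contradicts them. That contradiction (a negative projected donor
span, meaning the donor says the two flanks overlap) is resolved by
trimming up to `trimCap` (default 1 kb) from the left flank, and
otherwise reported as `donor_overlap_unresolvable`.

Patches longer than `maxPatchLen` (default 5 Mb) are refused: a donor
interval vastly longer than the gap usually signals a misjoin, not a
fill. Edits on one chromosome are applied right-to-left so earlier
coordinates stay valid during splicing; patched bases are emitted
uppercase (they carry no soft-masking evidence) while all surrounding
case is preserved. Every edit is recorded in a monotone liftover map, and
both junctions of every patch are kept for depth validation.

## Validation

Three independent lines, mirroring standard assembly QC practice:

* **Junction depth**: reads mapped to the patched assembly should cover
  every patch junction; `junctionCoverage()` requires a minimum depth
  over a ±window around each junction, clipped at chromosome ends.
* **k-mer QV**: with distinct canonical k-mers (lexicographic minimum of
  a k-mer and its reverse complement, default k = 21), the fraction of
  assembly k-mers found in the read set gives a per-base error estimate
  `1 - (shared/total)^(1/k)` and `QV = -10 log10(error)`, capped at 99
  when no k-mer is missing. Presence/absence rather than multiplicity
  keeps the estimator simple and is adequate at the scales the package
  simulates; it slightly underestimates error inside long tandem repeats,
  where a mutated locus does not remove the original k-mer from the
  assembly set.
* **Homozygous-variant rate**: variants called from reads against the
  patched assembly that are homozygous-alternate (GT 1/1 or 1|1, QUAL ≥
  30, DP ≥ 5 by default) are positions where the sample evidence
  contradicts the assembly; their count divided by assembly size is a
  direct base-level error proxy.

## Annotation

**Telomeres.** Both orientations of the vertebrate repeat
(TTAGGG/CCCTAA) are counted as exact non-overlapping matches in the
first and last `endWindow` = 10 kb; the call is based on the densest
`scanWindow` = 1 kb sliding window (fraction of bases covered by motif
copies, threshold 0.4). Windows touching the chromosome boundary may
shrink to half a window, so a dense terminal array of a few hundred bases
still scores its true density while interior windows — the only place a
random match could concentrate — keep the full-length denominator. Only
exact hexamers are counted; degenerate variants are deliberately out of
scope. A chromosome is **T2T** when it is gap-free and both ends carry a
telomere call.

**Centromere candidates.** A deliberately simple tandem-array scan, not
a reimplementation of dedicated centromere pipelines: a position is
"tandem" when its 21-mer recurs downstream at a spacing within
`periodRange` = [100, 2000] bp; the indicator is smoothed over a 10-kb
running window, the longest run at or above 0.5 becomes the candidate if
it is at least 10 kb long, and the monomer period is the modal spacing
inside it. Smoothing sets the localization resolution: boundaries land
where the windowed density crosses the threshold, about half a window
inside the true array edge, which is why recovery is scored as
reciprocal overlap rather than exact boundaries.

## Synteny and fusions

Filtered alignments are chained per (target, query, strand) group: a
chain extends while both the target-side and query-side gaps are at most
`maxChainGap` = 100 kb and query order is consistent with the strand
(decreasing for −). Chains shorter than `minBlockLen` = 10 kb are
dropped. Coverage summaries use interval unions so overlapping blocks are
never double-counted. A target chromosome is called a **fusion** when at
least two query chromosomes each cover at least `minFracEach` = 0.2 of
it — the pattern a fused chromosome shows against the unfused karyotype
of a related species. Gene-anchored microsynteny is out of scope.

### One-to-one filtering

The one-to-one filter mimics the effect of MUMmer's `delta-filter -1`:
no accepted record may overlap the other accepted records on its target
or query interval by more than `maxOverlapFrac` of its own length.
Selection maximizes total score *exactly* (branch-and-bound) inside
conflict components of up to 20 records and falls back to greedy
score-ordered acceptance inside larger ones. A pure greedy rule was
rejected because it is provably suboptimal on small instances (a single
high-scoring record can shadow two disjoint records whose scores sum
higher); after length/identity filtering, real whole-genome alignment
sets decompose into small components, so the exact path is the one that
almost always runs. Ties break by longer block, then (tname, tstart),
keeping the output deterministic.

## The simulator

Every input the toolkit consumes can be fabricated from a seeded
configuration, so the whole pipeline is testable with no external data.
Defaults are chosen to emulate a mammalian chromosome-level assembly
project at desk scale: five 1-Mb chromosomes; GC 0.42; 3-kb telomere
arrays (500 hexamer copies, C-rich motif leading the 5′ end); a 50-kb
centromeric array of a random 171-bp monomer with 1% per-copy
substitution (the length of the alpha-satellite monomer family); five
gaps of 200–2000 bp per chromosome; donor contigs of 150–400 kb, 30%
reverse-complemented; donor divergence 0 or 0.01 depending on the
experiment (1% is a realistic intra-species haplotype divergence upper
bound). Each generator draws from its own RNG substream derived from the
master seed, so adding a generator never perturbs another's output.

Donor fragmentation breakpoints are kept at least 10 kb from planted gap
edges by default, so every gap is spannable by a single contig — the
regime the round-trip property needs; anchor-failure statuses are
exercised with hand-built fixtures instead. True alignments are emitted
directly from provenance, which keeps tests free of aligner dependencies
and makes the expected patched sequence exactly computable.

What the simulator does *not* model: indels (so alignment projection is
exact in tests — real data exercises the interpolation error),
interspersed repeat families, read-length/error profiles of any real
instrument, and Hi-C evidence. Passing tests therefore demonstrate the
correctness of the bookkeeping — coordinates, orientation, splicing,
liftover, reporting — not robustness to structurally misleading
alignments, which remains the responsibility of the upstream aligner and
filter settings.

## Verified behavior at a glance

```{r roundtrip}
cfg <- simConfig(seed = 42, nChroms = 2, chromLen = 200000L,
                 telomereCopies = 100L, centromereArrayLen = 20000L,
                 nGapsPerChrom = 3L)
tr  <- simulateGenome(cfg)
deg <- degradeToScaffold(tr, cfg)
don <- makeDonor(tr, cfg, gaps = deg$gaps)
res <- fillGaps(deg$assembly, don$assembly, don$alignments)
res
identical(patchedAssembly(res), genomeSeqs(tr))
```

The test suite asserts this round trip at full scale across ten seeds,
plus: mismatches confined to patch intervals at 1% donor divergence
(pooled count inside a 99% binomial interval — a strict per-patch
interval over dozens of short patches would be expected to fail a
fraction of patches by construction, so the pooled rate is the
statistically meaningful check); oracle equivalence of gap discovery,
N50, one-to-one selection and liftover monotonicity; telomere sensitivity
1.0 with zero false positives over 100 chromosomes; centromere
localization at ≥ 90% reciprocal overlap with period within ±5 bp; the
QV closed form against an arbitrary-precision value; and fusion
sensitivity ≥ 0.95 with zero false calls on un-rearranged controls.

## Problem sizes

Simulated experiments run at 5 × 1 Mb chromosomes (the study-condition
default) for the fill pipeline, 20-kb chromosomes for telomere
screening, 150-kb chromosomes for centromere localization, and 3 ×
100-kb genomes for fusion simulations — sizes at which every property
above is measurable in seconds while remaining faithful to the
structures being modeled.

## Known limitations

* Substitution-only donor model in tests; indel-bearing donors shift
  patch coordinates by up to the alignment's indel imbalance.
* One donor assembly per run; reconciling several donors means running
  the pipeline once per donor in priority order.
* The centromere scan reports one candidate per chromosome (the longest
  qualifying run) and does not classify repeat families.
* QV uses distinct k-mers, so errors inside perfect long repeats are
  under-counted.
* No polishing: patched bases are donor bases verbatim.
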