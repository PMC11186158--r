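# gapmend

Reference-guided gap patching, validation and annotation for consensus
genome assemblies.

## What it is for

Chromosome-level assemblies usually retain N-gaps where one read
technology could not bridge a locus. When a second assembly of the same
species — another individual, another technology — is contiguous across
those loci, its sequence can be spliced into the gaps, yielding a
gap-free *consensus* assembly. gapmend is the reconciliation toolkit for
that strategy, aimed at assembly engineers who already have two
assemblies and a whole-genome alignment between them:

* **gap filling** — inventory N-gaps, choose a donor interval per gap
  from flank-anchored or gap-spanning alignments (PAF or MUMmer
  `show-coords -rTH`), splice patches in, and emit the patched FASTA, an
  AGP, a coordinate liftover (JSON) and a per-gap audit report;
* **validation** — read-depth checks at every patch junction, a k-mer
  based quality value, and a homozygous-variant error rate from a VCF;
* **annotation** — telomere calls from TTAGGG/CCCTAA density,
  telomere-to-telomere (T2T) classification, and a centromere-candidate
  scan based on k-mer recurrence periodicity;
* **comparative checks** — synteny block chaining against a related
  genome and detection of chromosome fusion events;
* **simulation** — seeded generators for truth genomes, gapped
  scaffolds, divergent donors, rearranged companion genomes, depth
  tracks and read k-mer sets, so every claim the package makes is
  testable without any external data.

## The model in brief

A gap is a maximal run of N. For each gap, anchors are filtered
alignments reaching within `flankWindow` of a gap edge; a single
spanning alignment is preferred, otherwise the best concordant
left/right anchor pair (same donor contig, same strand, donor-colinear,
maximal summed score) defines the patch as the projection of the gap
edges onto donor coordinates. Every failure mode is a recorded status,
not an error. The k-mer QV follows the shared-fraction estimator over
distinct canonical k-mers:

```
error = 1 - (shared / total)^(1/k),   QV = -10 * log10(error)
```

A chromosome is T2T iff it is gap-free with telomere calls at both ends.
A fusion is called when ≥ 2 query chromosomes each cover ≥ 20% of a
target chromosome in chained synteny blocks. Details and design
rationale are in `vignettes/consensus-gap-filling.Rmd`.

## Worked example

```r
library(gapmend)

cfg <- simConfig(seed = 42, nChroms = 2, chromLen = 200000L,
                 telomereCopies = 100L, centromereArrayLen = 20000L,
                 nGapsPerChrom = 3L)
tr  <- simulateGenome(cfg)       # truth genome with planted annotation
deg <- degradeToScaffold(tr, cfg)  # same genome with N-gaps punched in
don <- makeDonor(tr, cfg, gaps = deg$gaps)  # fragmented second individual

res <- fillGaps(deg$assembly, don$assembly, don$alignments)
res
#> GapFillResult: 2 sequence(s); gaps found 6, filled 6, unfilled 0
#>   residual gaps: 0

identical(patchedAssembly(res), genomeSeqs(tr))
#> [1] TRUE
```

Every planted gap was filled, no gaps remain, and — because the donor
here is divergence-0 — the patched assembly equals the truth genome
byte for byte. The per-gap report shows where each patch came from:

```r
patchReport(res)$perGap[1:3, c("chrom", "gap_start", "gap_end", "mode",
                               "donor_name", "orientation", "status")]
#>   chrom gap_start gap_end     mode    donor_name orientation  status
#> 1 chr01     34460   35503 spanning ctg_chr01_001           - planned
#> 2 chr01    142258  143677 spanning ctg_chr01_001           - planned
#> 3 chr01    164625  166448 spanning ctg_chr01_001           - planned
```

All three gaps on chr01 were spanned by one reverse-complemented donor
contig. Annotation and validation close the loop:

```r
t2tClassify(findGaps(patchedAssembly(res)),
            telomereScanAll(patchedAssembly(res)))
#>   chrom gap_free telomere_5p telomere_3p  t2t
#> 1 chr01     TRUE        TRUE        TRUE TRUE
#> 2 chr02     TRUE        TRUE        TRUE TRUE

rk <- makeDepthAndKmers(genomeSeqs(tr), seed = 42)  # error-free reads
kmerQV(kmerSet(patchedAssembly(res)), rk$kmers)$qv
#> [1] 99
```

Both chromosomes are T2T and the QV sits at the cap, as it must when the
read k-mer set contains every assembly k-mer.

## Command line

A thin dispatcher over the same functions is installed as `exec/gapmend`:

```sh
gapmend simulate --seed 42 --chroms 2 --chrom-len 200000 --out simdir
gapmend fill --target simdir/target.fa --donor simdir/donor.fa \
             --aln simdir/donor_vs_target.paf --out filled
gapmend stats --fasta filled.fa --json stats.json
gapmend telomeres --fasta filled.fa --out telomeres.tsv
```

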