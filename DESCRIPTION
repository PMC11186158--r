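Package: gapmend
Title: Reference-Guided Gap Patching and Validation for Consensus Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds gap-free "consensus" chromosome assemblies by patching
    N-gaps in a chromosome-level target assembly with sequence taken from a
    second (donor) assembly, guided by whole-genome alignments (PAF or MUMmer
    show-coords). Plans one patch per gap from flank-anchored or gap-spanning
    alignments, splices the donor sequence in, and emits the patched FASTA,
    an AGP of the new structure, a coordinate liftover and a per-gap report.
    Validates the result with junction read-depth checks, a k-mer based
    assembly quality value (QV) and a homozygous-variant error rate, and
    annotates it with telomere calls (TTAGGG/CCCTAA density),
    telomere-to-telomere status and centromere candidate arrays. Chains
    filtered alignments into synteny blocks against a related genome and
    detects chromosome fusion events. A seeded simulator fabricates truth
    genomes, gapped scaffolds, divergent donors, rearranged companion
    genomes, depth tracks and read k-mer sets so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
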