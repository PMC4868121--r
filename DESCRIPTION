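Package: esevol
Title: Exonic Splice Enhancer Density, Dinucleotide-Controlled Nulls, and
    Selection Tests in Coding Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans coding sequences for exonic splice enhancer (ESE) hexamer
    motifs and quantifies their enrichment and conservation while controlling
    for dinucleotide composition. Provides union-coverage motif densities at
    gene, paralog-family and pooled granularity; three null models
    (dinucleotide-pool random hexamer sets, windowed codon shuffles, and
    exhaustive per-motif dinucleotide permutations); empirical p-values and
    normalized densities; Nei-Gojobori synonymous rates inside codon-repaired
    motif blocks; SNP density and low minor-allele-frequency fractions at
    fourfold degenerate sites; mean-intron-size binned per-motif enrichment
    matrices with rank-trend classification; exon flank versus core positional
    contrasts; retrocopy calling, parent matching, ancestral junction mapping
    and leave-k-out resampling. A synthetic cohort generator with planted,
    protein-preserving motif excess, scaled synonymous divergence and rare
    variant excess makes every stage testable end to end without external
    genome extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
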