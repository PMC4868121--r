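# esevol

Quantifying exonic splice enhancer (ESE) motif enrichment and purifying
selection in coding sequence, with dinucleotide-controlled null models.

## The problem

ESEs are short exonic motifs — here literal hexamers — that recruit
splicing factors. Because they sit inside protein-coding sequence, raw
motif counts confound with nucleotide composition: purine-rich ESE-like
hexamers arise by chance more often in AT-rich genes, and GC content
itself varies systematically with gene architecture (intronless genes are
the most GC-rich). Asking whether a class of genes is enriched in ESEs,
or whether ESE positions evolve more slowly, therefore requires
composition-matched expectations throughout.

`esevol` is for molecular-evolution researchers who want that analysis
stack as tested, reusable functions:

* **Scanning and density.** Exact hexamer matching with union coverage
  (overlapping hits counted once); densities per gene, per paralogous
  family (one data point per family) or pooled (`find_hits`,
  `ese_density`, `cluster_families`).
* **Null models.** Control hexamer sets drawn from the real set's
  overlapping-dinucleotide pool (`build_control_sets`); windowed codon
  shuffles (`codon_shuffle`); exhaustive per-motif dinucleotide
  permutations — 60 controls for a hexamer with five distinct
  dinucleotides (`permutation_controls`).
* **Statistics.** Normalized density ND = (observed − null mean)/null
  mean; empirical p-values p = (n+1)/(m+1) with ties extreme; exact
  binomial tails; Goodman–Kruskal gamma with shuffle p; partial Spearman
  correlation; Holm step-down adjustment.
* **Selection tests.** Nei–Gojobori dS (Jukes–Cantor corrected) on
  codon-repaired motif blocks concatenated across genes, against control
  motif sets (`concatenated_ds`, `extract_ese_blocks`); SNP density at
  fourfold degenerate sites and low-MAF (< 1/2000) fractions inside motif
  coverage (`snp_statistics`).
* **Architecture and retrocopies.** Mean-intron-size quantile binning
  (intronless genes form bin 0), bins × motifs ND matrices with
  permutation-control medians, per-motif trend classification, exon
  flank/core contrasts, retrocopy calling, parent matching by dN,
  ancestral junction mapping, and leave-k-out resampling.
* **Synthetic cohorts.** `make_cohort` generates genes with a negative
  GC4 vs exon-number gradient, protein-preserving planted motif excess
  with a 5′ exon-end bias, orthologs whose synonymous rate is scaled
  inside motif hits, SNPs with a rare-allele excess inside motifs, and
  retrocopies inheriting parental motifs — so every stage is testable
  without external genome extracts.

The packaged 84-hexamer motif set is a **synthetic**, purine/adenine-rich
stand-in with the composition profile of published high-confidence ESE
sets; supply a real motif file (one hexamer per line, `read_motifs`) for
real analyses.

## Worked example

```r
library(esevol)

cfg    <- synthetic_config(n_genes = 60, seed = 42)
cohort <- make_cohort(cfg)
report <- run_pipeline(run_config(cohort = cohort, n_control_sets = 200,
                                  n_control_sets_ds = 100, seed = 42))
print(report)
```

```
esevol pipeline report (seed 42 , 60 genes)
  intronless: median density 0.1305, ND 0.262, enrichment p 0.00995
  intron_containing: median density 0.1399, ND 0.309, enrichment p 0.00498
  dS in motif regions: 0.05429 (normalized -0.161, p 0.0297)
  broad retrocopy calls: 3
```

Reading the output: 13.05% of intronless CDS bases fall under an ESE-like
hexamer, a 26% excess (ND 0.262) over the mean of 200
dinucleotide-matched control sets, with an empirical enrichment p of
0.00995 — the generator planted a 25% excess, which is recovered. The
concatenated synonymous rate inside motif regions is 0.054, 16% below the
control expectation (normalized dS −0.161, one-tailed p 0.0297),
reflecting the configured 0.8 scaling of the synonymous rate inside motif
hits. The three genes generated as retrocopies are recovered by the
≥ 50% annotation-overlap rule. `report$selection$snp` additionally holds
the SNP density at covered fourfold degenerate sites and the low-MAF
fraction (here 0.49 of covered segregating sites are rare, elevated over
controls with p 0.0099, reflecting the configured twofold rare-allele
excess).

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --simulate 60 --seed 42 --out-dir results/
Rscript inst/scripts/run_pipeline.R --cds cds.fasta --motifs motifs.txt --out-dir results/
```

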