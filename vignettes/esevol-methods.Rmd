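---
title: "Motif enrichment and selection in coding sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment and selection in coding sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Exonic splice enhancers (ESEs) are short motifs — treated here as literal
hexamers — that promote splice-site recognition, classically through SR
protein binding. Because they live inside coding sequence, their abundance
confounds with amino-acid content and nucleotide composition: purine-rich
ESE-like hexamers occur more often in AT-rich sequence purely by chance.
Any claim that a class of genes (say, intronless genes, or genes with
large introns) is enriched or depleted in ESEs therefore has to be made
*relative to a composition-matched expectation*, and any claim that ESE
positions are conserved has to compare evolutionary rates inside motif
hits with a matched null.

`esevol` implements that analysis stack: exact hexamer scanning with
union coverage, three dinucleotide-aware null models, normalized density
(ND) with empirical p-values, synonymous-rate (dS) estimation inside
codon-repaired motif blocks, polymorphism statistics at fourfold
degenerate sites, gene-architecture stratified per-motif enrichment, exon
flank/core positional contrasts, and retrocopy analyses. A synthetic
cohort generator with known planted structure makes every stage testable
end to end.

## Densities and normalization

The **ESE density** of a sequence is the proportion of its nucleotides
covered by at least one motif hit; bases under two or more overlapping
hits count once (`find_hits`). Paralogous gene families, found as
connected components of a sequence-similarity graph (`cluster_families`),
are single data points: member densities are averaged (`ese_density`,
mode `family_mean`). Pooled densities (summed covered bases over summed
lengths) are used for short sequences such as 69-bp exon windows, where
per-sequence medians would collapse to zero.

The primary null model (`build_control_sets`) redraws each hexamer as a
concatenation of three dinucleotides sampled with replacement from the
pool of the real set's overlapping dinucleotides (five per motif; pairs
spanning a junction between concatenated motifs are excluded because they
would depend on an arbitrary concatenation order). Hexamers identical to
a real motif are rejected and redrawn. Whether duplicates within one
control set should be allowed is not dictated by the sampling story; we
default to allowing them and expose `allow_duplicates`. The
**normalized density** is ND = (observed − null mean)/null mean, and
empirical p-values are (n+1)/(m+1) with ties counted as extreme
(`empirical_p`), so the smallest attainable p with 10,000 simulants is
9.999 × 10⁻⁵ and a p of exactly 0 is impossible.

Two further nulls serve specific stages: windowed codon shuffles
(`codon_shuffle`, 294-bp subregions, leftover bases merged into the
3′-most subregion) preserve codon usage locally, and per-motif
**dinucleotide permutations** (`permutation_controls`) enumerate every
hexamer constructible from an ordered selection of three of the motif's
five overlapping dinucleotides — exactly 60 when the five are distinct,
fewer for degenerate motifs. The identity tiling reproduces the motif
itself and is retained by default, since the printed count of 60 includes
it; `include_self = FALSE` removes it.

## Synonymous rates inside motif blocks

Contiguous runs of motif-covered bases are made codon-complete before
rate estimation (`extract_ese_blocks`): an incomplete final codon is
trimmed, and an incomplete initial codon is expanded with one or two
upstream bases. Expansion could import a spurious non-motif synonymous
site at codon position 1 — only leucine and arginine codons have
first-position degeneracy — so an expanded initial Leu/Arg codon has its
first two bases rewritten to `GA` when its third base is 2-fold
degenerate and `GC` when 4-fold, in both rows (unless the ortholog codon
is an indel). The rewrite preserves the third-position degeneracy class
(TTA→GAA stays 2-fold, CTG→GCG stays 4-fold) and therefore keeps the
motif-internal synonymous site while silencing position 1.

Rates are Nei–Gojobori (1986) counts with Jukes–Cantor correction
(`pairwise_codon_rates`): fractional site counts averaged over the two
rows, mutations to stop codons treated as nonsynonymous, multi-hit codons
averaged over mutational paths that avoid stop intermediates, and codon
columns containing gaps or stops excluded. `concatenated_ds` pools the
counts over all blocks of all genes before the correction, which makes
the estimate invariant to concatenation order; the same machinery applied
to each control motif set yields the null, the normalized dS, and a
one-tailed empirical p for a reduction. PAML's codeml (model = 0) is the
natural reference estimator for users who have it installed; the
in-package estimator is validated against an independent path-enumeration
implementation in the test suite instead of against codeml.

## Polymorphism statistics

`snp_statistics` computes (i) SNP density at fourfold degenerate sites
inside motif coverage — the count of SNPs at covered 4-fold sites over
the number of covered 4-fold sites; both a synonymous-only and an all-SNP
numerator are reported because annotation sources differ in what they
list — and (ii) the fraction of covered segregating sites with minor
allele frequency below 1/2,000 (an adjustable, admittedly arbitrary
threshold). With paralog families present, each of 10 replicates redraws
one random member per family through a named substream, and medians of
the statistics and of their empirical p-values are reported. The
enrichment tails are one-sided in opposite directions: purifying
selection predicts *fewer* SNPs but *rarer* ones inside motifs.

## Architecture stratification

Data points are binned by family-averaged mean intron size
(`assign_bins`): points at exactly 0 (intronless) form bin 0 and the rest
are cut at every 1/48th quantile by default, 49 bins in all, with
boundary ties going deterministically to the lower bin. A 38-bin mode
(`n_quantile_bins = 37`) is the natural choice for runs that include
retrocopies with a smaller intronless sample. `motif_bin_matrix` builds
the bins × motifs matrix of pooled densities and normalizes each cell
against the median of that motif's ≤ 60 dinucleotide-permutation
controls; cells with a zero simulant median are marked undefined rather
than infinite, and trend tests drop those rows. Because permutation
controls of a motif can themselves be members of the real set — which
penalizes motifs whose dinucleotide composition resembles the set-wide
composition — the fraction of self-overlapping controls is reported per
motif as a diagnostic. `motif_trend_tests` correlates each column with
the bin indices (Spearman), Holm-adjusts across motifs (our own
step-down implementation, cross-checked against `p.adjust`), and labels
motifs positive/negative/nonsignificant.

For positional structure, internal fully-coding exons of at least 211 bp
(69 × 3 + 2 × 2, the minimum that guarantees three codon-aligned 69-bp
windows after trimming at most two bases at each end) are split into an
upstream flank, a core and a downstream flank (`exon_windows`). When the
codon gap between the flanks minus 23 codons is odd, the core sits one
codon closer to the 5′ end (the *n* vs *n* + 3 rule); parity is evaluated
in codons, consistent with that codon-sized offset, and the three windows
are disjoint by construction. `flank_core_contrast` compares flank and
core enrichment between two motif subsets. The paper-style summary is
the ratio of additive NDs, but the significance computation uses the
ratio of fold enrichments (observed/null mean), which remains stable
where a control set's additive ND crosses zero.

## Retrocopies

`broad_retrocopy_calls` marks genes overlapped ≥ 50% by retrocopy
annotations; `strict_parent_match` aligns candidates at the protein
level, back-threads to codons and requires dN < 0.2 with a >50% length
ratio, taking the argmin-dN candidate (ties to the smaller identifier).
`junction_proximity` maps each noninitial parent-exon start through the
alignment, drops junctions whose 30-bp probe is less than half intact
(indel-free), and reports the fraction of motif hits whose first base
lies within 50 bp (inclusive) of a surviving pseudo-junction.
`leave_k_out` compares the density/significance change caused by removing
the called retrocopies with the distribution over removals of k random
genes, reusing precomputed per-gene coverage so that each iteration is a
column sum.

## The synthetic generator

`make_cohort` emulates the statistical features the analysis relies on,
with defaults that describe the study conditions:

* **Architecture and composition.** Exon counts follow
  1 + NB(mu = 5, size = 2) (a mix of intronless and multi-exon genes);
  CDS lengths are uniform multiples of 3 between 450 and 2,400 bp
  (mammalian scale); intron lengths are log-normal (median 1.5 kb).
  Per-gene target GC4 is 0.60 − 0.01·(exons − 1) plus N(0, 0.05) noise,
  realized by biasing third-base choices within synonymous codon
  families — reproducing the negative GC4 vs exon-number gradient that
  motivates dinucleotide normalization in the first place.
* **Planting.** Motif hits are added by synonymous codon rewriting only,
  so the protein and ORF validity are invariant by construction. Few
  motifs are synonymously realizable at any given position (about 0.4%
  per random motif–position pair), so the planter samples a position and
  tries the motif set in random order, which biases planted motifs
  toward protein-compatible ones — as real ESE occupancy must be.
  Planting continues until scanned coverage exceeds the gene's
  pre-planting coverage by `planted_nd` (default 0.25); the pre-planting
  coverage stands in for the dinucleotide expectation, which matches it
  for unplanted sequence. Positions in the first 69 bp of an exon carry
  weight `end_bias` (default 2), the last 69 bp half of it.
* **Divergence, SNPs, retrocopies.** Orthologs are evolved by
  synonymous-only substitution with per-site probability
  `ds_background` (default 0.065) times `ese_ds_scaling` (default 0.8)
  inside motif hits; SNP positions segregate at `snp_rate` (0.01) with a
  rare-allele (MAF < 1/2,000) probability of 0.2, multiplied by
  `rare_excess` (2) inside hits; 5% of the cohort are retrocopies that
  copy a multi-exon parent's CDS verbatim and inherit its motifs.

Every stage draws from a named substream of the master seed
(`substream_seed`), so identical seeds give byte-identical cohorts and
stages can be re-run independently.

What the generator does **not** emulate: real intron sequence,
splice-site strength, expression, amino-acid composition of real
proteomes, linkage between SNPs, or CpG/isochore structure. Passing tests
therefore demonstrate that the statistics recover planted effects under
composition-realistic randomness, not that any particular biological
dataset shows those effects.

## Numerical choices and problem sizes

* Empirical p-values never return 0; the floor is 1/(m + 1).
* ND and normalized dS are undefined-marked (NA) when the null mean is
  nonpositive; they are never reported as infinities.
* dN/dS is undefined-marked when dS = 0; such pairs pass ratio-based
  filters (they cannot exceed a threshold). Human-mode ortholog filtering
  drops pairs with dS ≥ 0.2 or dN/dS ≥ 0.5; mouse-mode keeps pairs with
  dS < 0.3 and dN/dS < 0.5. Both modes are exposed because the two
  filters legitimately differ.
* Exon-number trend tests (`exon_number_trend`) exclude data points whose
  rounded exon-number class holds fewer than 50 points, because sparse
  classes contribute disproportionate rank-trend noise; the threshold is
  an argument.
* Similarity edges for family clustering use a shared 14-mer prescreen
  followed by local alignment (match 1, mismatch −2, gap 5/2) with a
  default score threshold of 40 — conservative enough that unrelated
  simulated genes remain singletons while retrocopy–parent pairs always
  connect.
* The test suite's simulation experiments are sized for a desk machine:
  parameter recovery of the dS reduction uses one 200-gene cohort against
  1,000 control sets; the null calibration uses 50 replicate 25-gene
  cohorts against 99 distinct-member control sets each (distinct members
  because the observed set also has distinct members — exchangeability
  is what the calibration tests); trend classification uses 13 bins of
  12 genes and a 24-motif set. At these sizes the recovery experiment
  has a standard error of roughly two percentage points on the recovered
  reduction.

## Known limitations

* Exact matching only: no position-weight matrices, no RNA-structure
  context, no IUPAC wildcards.
* The packaged 84-hexamer motif set is a synthetic, purine/adenine-rich
  stand-in with the composition profile of published high-confidence ESE
  sets; analyses of real data should supply the real motif file
  (`read_motifs`).
* The NG86 estimator assumes equal base frequencies and no
  transition/transversion bias (Jukes–Cantor); for strongly diverged
  pairs (pS ≥ 3/4) rates are undefined-marked rather than extrapolated.
* Summing per-motif covered bases across motifs double-counts bases
  shared by different motifs, so per-motif matrix rows can sum to more
  than the union-coverage density; the two agree only for non-overlapping
  motif sets.
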