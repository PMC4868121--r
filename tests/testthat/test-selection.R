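test_that("block repair follows the Leu/Arg rewrite rule", {
  # mask starting at the 3rd base of TTA (Leu, 2-fold third) -> GAA
  focal <- paste0("TTA", "GAAGAA")  # mask covers positions 3..9 (1-based)
  orth <- focal
  mask <- c(FALSE, FALSE, rep(TRUE, 7))
  bl <- extract_ese_blocks(focal, orth, mask)
  expect_length(bl$blocks, 1)
  expect_equal(substr(bl$blocks[[1]]$focal, 1, 3), "GAA")
  expect_equal(bl$repaired_positions, c(0L, 1L))
  # CTG (Leu, 4-fold third) -> GCG
  focal2 <- paste0("CTG", "GAAGAA")
  bl2 <- extract_ese_blocks(focal2, focal2, c(FALSE, FALSE, rep(TRUE, 7)))
  expect_equal(substr(bl2$blocks[[1]]$focal, 1, 3), "GCG")
  # codon-aligned mask: no repair, block equals the masked subsequence
  focal3 <- paste0("ATG", "GAAGAAGCT", "TAA")
  mask3 <- c(rep(FALSE, 3), rep(TRUE, 9), rep(FALSE, 3))
  bl3 <- extract_ese_blocks(focal3, focal3, mask3)
  expect_equal(bl3$blocks[[1]]$focal, "GAAGAAGCT")
  expect_length(bl3$repaired_positions, 0)
  # incomplete final codon is trimmed
  mask4 <- c(rep(FALSE, 3), rep(TRUE, 8), rep(FALSE, 4))
  bl4 <- extract_ese_blocks(focal3, focal3, mask4)
  expect_equal(bl4$blocks[[1]]$focal, "GAAGAA")
})

test_that("repair preserves the third-position degeneracy class", {
  leu_arg <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG",
               "CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
  for (cod in leu_arg) {
    focal <- paste0(cod, "GAAGAA")
    mask <- c(FALSE, FALSE, rep(TRUE, 7))
    rep_cod <- substr(extract_ese_blocks(focal, focal, mask)$blocks[[1]]$focal,
                      1, 3)
    deg_before <- annotate_degeneracy(cod)[3]
    deg_after <- annotate_degeneracy(rep_cod)[3]
    expect_equal(deg_after, deg_before)
    expect_equal(substr(rep_cod, 3, 3), substr(cod, 3, 3))
    expect_equal(substr(rep_cod, 1, 2),
                 if (deg_before == 2) "GA" else "GC")
  }
})

test_that("ortholog indels suppress the ortholog-side rewrite", {
  focal <- paste0("TTA", "GAAGAA")
  orth <- paste0("T-A", "GAAGAA")
  bl <- extract_ese_blocks(focal, orth, c(FALSE, FALSE, rep(TRUE, 7)))
  expect_equal(substr(bl$blocks[[1]]$focal, 1, 3), "GAA")
  expect_equal(substr(bl$blocks[[1]]$ortholog, 1, 3), "T-A")
})

test_that("repaired blocks translate without internal stops", {
  set.seed(12)
  cfg <- tiny_config(4)
  co <- make_cohort(cfg)
  for (g in co$genes$gene_id[1:5]) {
    a <- co$ortholog_pairs[[g]]
    mask <- find_hits(a$focal, cfg$motif_set)$coverage
    bl <- extract_ese_blocks(a$focal, a$ortholog, mask)
    for (b in bl$blocks) {
      aa <- translate_cds(b$focal)
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    }
  }
})

test_that("the concatenated dS engine agrees with block extraction", {
  set.seed(33)
  cfg <- tiny_config(9)
  co <- make_cohort(cfg)
  aln <- co$ortholog_pairs[1:8]
  ds <- concatenated_ds(aln, cfg$motif_set)
  S <- Sd <- 0
  for (a in aln) {
    mask <- find_hits(a$focal, cfg$motif_set)$coverage
    bl <- extract_ese_blocks(a$focal, a$ortholog, mask)
    for (b in bl$blocks) {
      r <- pairwise_codon_rates(b$focal, b$ortholog)
      S <- S + r$S
      Sd <- Sd + r$Sd
    }
  }
  expect_equal(unname(ds$counts["S"]), S, tolerance = 1e-10)
  expect_equal(unname(ds$counts["Sd"]), Sd, tolerance = 1e-10)
  # counts are additive, so gene order cannot matter
  ds_rev <- concatenated_ds(rev(aln), cfg$motif_set)
  expect_equal(ds$observed_ds, ds_rev$observed_ds)
})

test_that("identical rows give dS 0 and the floor p-value", {
  set.seed(2)
  cfg <- tiny_config(5, ds_background = 0)
  co <- make_cohort(cfg)
  ctrl <- build_control_sets(cfg$motif_set, 20, seed = 1)
  ds <- concatenated_ds(co$ortholog_pairs, cfg$motif_set, ctrl)
  expect_equal(ds$observed_ds, 0)
  # every control region also has dS 0 and ties count as extreme, so the
  # one-tailed reduction p is 1 (no evidence of slower evolution)
  expect_true(all(ds$null_ds == 0))
  expect_equal(ds$p, 1)
  expect_error(concatenated_ds(list(), cfg$motif_set), "no alignments")
})

test_that("SNP statistics count 4-fold sites and low-MAF fractions", {
  # one gene, hand-built: mask the middle GCT codons
  cds <- paste0("ATG", strrep("GCT", 10), "TAA")
  genes <- data.frame(gene_id = "g", cds = cds)
  motifs <- "GCTGCT"
  # 4-fold sites under the mask: every GCT third position (mask covers all)
  snps <- data.frame(gene_id = "g",
                     cds_pos = c(5L, 8L, 11L, 14L),  # third positions
                     maf = c(0.0004, 0.01, 0.2, 0.3),
                     consequence = "synonymous")
  st <- snp_statistics(genes, snps, motifs)
  expect_equal(st$low_maf_fraction, 0.25)
  # 4 synonymous SNPs at the 10 masked 4-fold sites
  expect_equal(st$snp_density_4d, 0.4)
  expect_equal(st$snp_density_4d_all, 0.4)
  # no SNPs in mask -> undefined-marked
  st0 <- snp_statistics(genes,
                        data.frame(gene_id = "g", cds_pos = 0L, maf = 0.1,
                                   consequence = "nonsynonymous")[0, ],
                        motifs)
  expect_true(is.na(st0$low_maf_fraction))
  expect_error(
    snp_statistics(genes, data.frame(gene_id = "g", cds_pos = 500L,
                                     maf = 0.1, consequence = "synonymous"),
                   motifs),
    "outside CDS")
})

test_that("rare-allele excess inside motifs is recovered", {
  set.seed(44)
  cfg <- synthetic_config(n_genes = 15, snp_rate = 0.05, rare_excess = 3,
                          cds_length_law = function(n)
                            3L * sample(200:300, n, replace = TRUE),
                          seed = 61)
  co <- make_cohort(cfg)
  inside <- outside <- c(low = 0, n = 0)
  for (g in co$genes$gene_id) {
    mask <- find_hits(co$genes$cds[co$genes$gene_id == g],
                      cfg$motif_set)$coverage
    s <- co$snps[co$snps$gene_id == g, ]
    if (nrow(s) == 0) next
    m <- mask[s$cds_pos + 1]
    low <- s$maf < cfg$maf_threshold
    inside <- inside + c(sum(low & m), sum(m))
    outside <- outside + c(sum(low & !m), sum(!m))
  }
  expect_gt(inside["low"] / inside["n"], outside["low"] / outside["n"])
})
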