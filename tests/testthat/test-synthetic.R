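test_that("empty and invalid configurations are handled", {
  co <- make_cohort(synthetic_config(n_genes = 0))
  expect_equal(nrow(co$genes), 0)
  expect_equal(nrow(co$truth), 0)
  expect_length(co$ortholog_pairs, 0)
  expect_error(synthetic_config(ese_ds_scaling = 1.5))
  expect_error(synthetic_config(snp_rate = -0.1))
  # coverage demanded beyond 1 is rejected with a diagnostic
  expect_error(make_cohort(tiny_config(1, planted_nd = 400)),
               "infeasible config")
})

test_that("cohorts are byte-identical under a seed and differ across seeds", {
  c1 <- make_cohort(tiny_config(5))
  c2 <- make_cohort(tiny_config(5))
  expect_identical(c1$genes, c2$genes)
  expect_identical(c1$ortholog_pairs, c2$ortholog_pairs)
  expect_identical(c1$snps, c2$snps)
  c3 <- make_cohort(tiny_config(6))
  expect_false(identical(c1$genes$cds, c3$genes$cds))
})

test_that("every generated CDS is a valid ORF", {
  co <- make_cohort(tiny_config(8))
  for (s in co$genes$cds) {
    v <- validate_cds(s)
    expect_true(v$pass)
  }
  expect_true(all(co$genes$cds_length == nchar(co$genes$cds)))
  expect_equal(co$genes$intron_density,
               (co$genes$exon_count - 1) / co$genes$cds_length)
  expect_true(all((co$genes$mean_intron_size == 0) ==
                    (co$genes$exon_count == 1)))
  # truth covers every gene; orthologs and SNP genes exist in the table
  expect_setequal(co$truth$gene_id, co$genes$gene_id)
  expect_setequal(names(co$ortholog_pairs), co$genes$gene_id)
  expect_true(all(co$snps$gene_id %in% co$genes$gene_id))
})

test_that("a negative GC4 slope yields a negative realized correlation", {
  cfg <- synthetic_config(n_genes = 300, planted_nd = 0, ds_background = 0,
                          snp_rate = 0, retro_fraction = 0, seed = 99)
  co <- make_cohort(cfg)
  ct <- suppressWarnings(cor.test(co$genes$gc4, co$genes$exon_count,
                                  method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("planting is synonymous and hits the coverage target", {
  set.seed(3)
  cds <- paste0("ATG", random_sense_cds(150), "TAA")
  for (m in int3_like_motifs()[c(1, 10, 30)]) {
    r <- plant_motif_hits(cds, m, 4, seed = 7)
    expect_equal(translate_cds(r$cds), translate_cds(cds))
    for (s in r$planted_starts)
      expect_equal(substr(r$cds, s + 1, s + 6), m)
  }
  # cohort-level: realized excess over dinucleotide controls tracks the
  # configured planted_nd
  cfg <- synthetic_config(n_genes = 25, planted_nd = 0.3,
                          ds_background = 0, snp_rate = 0, seed = 13)
  co <- make_cohort(cfg)
  idx <- lapply(co$genes$cds, esevol:::hit_index)
  obs <- sum(vapply(idx, function(ix) as.numeric(esevol:::.covered_bases(
    esevol:::.merge_hit_runs(esevol:::.starts_for_set(ix, cfg$motif_set)))),
    numeric(1))) / sum(co$genes$cds_length)
  ctrl <- build_control_sets(cfg$motif_set, 60, seed = 2)
  null <- colSums(esevol:::.coverage_matrix(idx, ctrl)) /
    sum(co$genes$cds_length)
  nd <- obs / mean(null) - 1
  expect_gt(nd, 0.15)
  expect_lt(nd, 0.45)
})

test_that("ortholog evolution is synonymous-only with scaled motif rates", {
  cfg <- tiny_config(21)
  co <- make_cohort(cfg)
  for (a in co$ortholog_pairs) {
    expect_equal(nchar(a$focal), nchar(a$ortholog))
    expect_equal(translate_cds(a$focal), translate_cds(a$ortholog))
  }
  # zero rate: identical copy
  a0 <- evolve_ortholog(co$genes$cds[1],
                        tiny_config(1, ds_background = 0))
  expect_identical(a0$focal, a0$ortholog)
  # scaling 0.5 recovered from the inside/outside rate ratio
  cfg5 <- synthetic_config(n_genes = 40, ese_ds_scaling = 0.5,
                           planted_nd = 0.3, snp_rate = 0,
                           retro_fraction = 0, seed = 77)
  co5 <- make_cohort(cfg5)
  ds_in <- concatenated_ds(co5$ortholog_pairs, cfg5$motif_set)
  S <- Sd <- 0
  for (a in co5$ortholog_pairs) {
    dsi <- esevol:::ds_index(a$focal, a$ortholog)
    mask <- find_hits(a$focal, cfg5$motif_set)$coverage
    cnt <- esevol:::.run_counts(dsi, esevol:::.logical_runs(!mask))
    S <- S + cnt["S"]; Sd <- Sd + cnt["Sd"]
  }
  ds_out <- esevol:::.jc_correct(Sd / S)
  expect_equal(unname(ds_in$observed_ds / ds_out), 0.5, tolerance = 0.1)
})

test_that("SNP simulation respects rates and degeneracy", {
  cfg <- tiny_config(31, snp_rate = 0)
  expect_equal(nrow(simulate_snps("ATGGAAGCTTAA", cfg)), 0)
  cfg2 <- tiny_config(32, snp_rate = 0.05)
  co <- make_cohort(cfg2)
  s <- co$snps
  expect_true(all(s$maf > 0 & s$maf <= 0.5))
  # alleles are degeneracy consistent: synonymous SNPs do not change the
  # amino acid
  for (i in sample(nrow(s), min(40, nrow(s)))) {
    cds <- co$genes$cds[co$genes$gene_id == s$gene_id[i]]
    pos <- s$cds_pos[i] + 1
    expect_equal(substr(cds, pos, pos), s$ref[i])
    mut <- cds
    substr(mut, pos, pos) <- s$alt[i]
    same <- translate_cds(mut) == translate_cds(cds)
    expect_equal(same, s$consequence[i] == "synonymous")
  }
})

test_that("retrocopies inherit the parent CDS and motif content", {
  parent <- list(gene_id = "P", exon_count = 3,
                 cds = paste0("ATG", random_sense_cds(120), "TAA"))
  rc <- derive_retrocopy(parent, n_substitutions = 0)
  expect_equal(rc$gene$cds, parent$cds)
  expect_equal(rc$gene$exon_count, 1L)
  motifs <- int3_like_motifs()
  expect_equal(find_hits(rc$gene$cds, motifs)$covered,
               find_hits(parent$cds, motifs)$covered)
  # its own annotation calls it broad with full overlap
  calls <- broad_retrocopy_calls(
    data.frame(gene_id = "R", chrom = "chrS", start = rc$interval$start,
               end = rc$interval$end),
    rc$interval)
  expect_equal(calls$overlap_fraction, 1)
  expect_equal(calls$tier, "broad")
  expect_error(derive_retrocopy(list(gene_id = "x", cds = "ATGTAA",
                                     exon_count = 1)),
               "at least 2 exons")
})
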