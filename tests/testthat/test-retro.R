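test_that("broad calls use inclusive union overlap fractions", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(0, 100, 0), end = c(1000, 1000, 500))
  retro <- data.frame(chrom = "chr1", start = c(0, 0), end = c(500, 500))
  calls <- broad_retrocopy_calls(genes, retro)
  expect_equal(calls$overlap_fraction, c(0.5, 400 / 900, 1))
  expect_equal(calls$tier, c("broad", "none", "broad"))
  # union, not double counting
  retro2 <- data.frame(chrom = "chr1", start = c(0, 200), end = c(400, 600))
  expect_equal(broad_retrocopy_calls(genes[3, ], retro2)$overlap_fraction, 1)
  expect_error(broad_retrocopy_calls(
    data.frame(gene_id = "x", chrom = "chr1", start = 10, end = 10), retro),
    "malformed")
  # monotone: a stricter threshold never adds calls
  for (f in c(0.3, 0.5, 0.7)) {
    lo <- broad_retrocopy_calls(genes, retro, min_fraction = f)
    hi <- broad_retrocopy_calls(genes, retro, min_fraction = f + 0.2)
    expect_true(all(which(hi$tier == "broad") %in%
                      which(lo$tier == "broad")))
  }
})

test_that("strict parent matching filters by length ratio and dN", {
  set.seed(71)
  cds <- paste0("ATG", random_sense_cds(100), "TAA")
  # a diverged candidate: heavy nonsynonymous mutation pushes dN over 0.2
  diverge <- function(s, n) {
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    sense <- names(GENCODE)[GENCODE != "*" & !startsWith(names(GENCODE), "ATG")]
    idx <- sample(2:(length(codons) - 1), n)
    codons[idx] <- sample(sense, n, replace = TRUE)
    paste(codons, collapse = "")
  }
  far <- diverge(cds, 60)
  near <- diverge(cds, 2)
  short <- substr(cds, 1, 120)
  res <- strict_parent_match(list(gene_id = "R", cds = cds),
                             data.frame(gene_id = c("far", "near", "short"),
                                        cds = c(far, near, short)))
  expect_equal(res$tier, "strict")
  expect_equal(res$parent_id, "near")
  expect_lt(res$parent_dn, 0.2)
  expect_false("short" %in% res$candidates$gene_id)
  # only a distant candidate: broad tier, no parent
  res2 <- strict_parent_match(list(gene_id = "R", cds = cds),
                              data.frame(gene_id = "far", cds = far))
  expect_equal(res2$tier, "broad")
  expect_true(is.na(res2$parent_id))
  # argmin ties broken by lexicographic id
  res3 <- strict_parent_match(list(gene_id = "R", cds = cds),
                              data.frame(gene_id = c("zz", "aa"),
                                         cds = c(cds, cds)))
  expect_equal(res3$parent_id, "aa")
})

test_that("junction mapping respects the intactness rule", {
  # identical alignment: junction at 100 maps to itself
  s <- strrep("A", 300)
  jp <- junction_proximity(100L, list(focal = s, ortholog = s),
                           hit_starts = c(60L, 160L))
  expect_equal(jp$junctions_retro, 100L)
  expect_equal(jp$fraction_near, 0.5)  # |60-100| = 40 <= 50; |160-100| > 50
  expect_equal(junction_proximity(100L, list(focal = s, ortholog = s),
                                  c(50L, 150L))$fraction_near, 1)
  # probe region mostly deleted in the retrocopy: junction dropped
  f <- paste0(strrep("A", 100), strrep("-", 25), strrep("A", 175))
  o <- strrep("A", 300)
  jp2 <- junction_proximity(100L, list(focal = f, ortholog = o),
                            hit_starts = c(90L))
  expect_length(jp2$junctions_retro, 0)
  expect_true(is.na(jp2$fraction_near))
  # no hits: undefined
  expect_true(is.na(junction_proximity(100L, list(focal = s, ortholog = s),
                                       integer(0))$fraction_near))
})

test_that("leave-k-out ranks a planted removal in the tail", {
  # toy statistic: mean of per-gene scores, "p" slot unused (constant)
  scores <- c(rep(10, 5), rep(1, 45))
  names(scores) <- paste0("g", 1:50)
  statistic <- function(ids) c(mean(scores[ids]), 0.5)
  lko <- leave_k_out(names(scores), statistic,
                     observed_removal = paste0("g", 1:5),
                     iterations = 200, seed = 4)
  # removing the five high-score genes drops the mean more than chance
  expect_lt(lko$p_nd, 0.05)
  expect_equal(unname(lko$true_delta["delta_nd"]),
               mean(scores[6:50]) - mean(scores))
  # k = 0 gives degenerate all-zero deltas
  lko0 <- leave_k_out(names(scores), statistic, character(0), k = 0,
                      iterations = 10, seed = 1)
  expect_true(all(lko0$null_delta == 0))
  expect_error(leave_k_out(names(scores), statistic, names(scores)),
               "smaller")
  # identity statistic: degenerate distributions
  lko1 <- leave_k_out(names(scores), function(ids) c(1, 1),
                      observed_removal = paste0("g", 1:5),
                      iterations = 20, seed = 2)
  expect_true(all(lko1$null_delta == 0))
  expect_equal(unname(lko1$true_delta), c(0, 0))
})

test_that("removing motif-rich retrocopies shifts the cohort ND", {
  set.seed(88)
  cfg <- synthetic_config(n_genes = 40, planted_nd = 0, ds_background = 0,
                          snp_rate = 0, retro_fraction = 0,
                          cds_length_law = function(n)
                            3L * sample(150:250, n, replace = TRUE),
                          seed = 55)
  co <- make_cohort(cfg)
  genes <- co$genes
  rich <- genes$gene_id[1:6]
  for (g in rich) {
    i <- which(genes$gene_id == g)
    for (m in cfg$motif_set[c(3, 11, 25)])
      genes$cds[i] <- insert_motif(genes$cds[i], m, 4)
  }
  idx <- lapply(genes$cds, esevol:::hit_index)
  names(idx) <- genes$gene_id
  lens <- setNames(nchar(genes$cds), genes$gene_id)
  ctrl <- build_control_sets(cfg$motif_set, 60, seed = 6)
  cov_real <- setNames(esevol:::.coverage_matrix(idx, list(cfg$motif_set))[, 1],
                       genes$gene_id)
  cov_ctrl <- esevol:::.coverage_matrix(idx, ctrl)
  rownames(cov_ctrl) <- genes$gene_id
  statistic <- function(ids) {
    obs <- sum(cov_real[ids]) / sum(lens[ids])
    null <- colSums(cov_ctrl[ids, , drop = FALSE]) / sum(lens[ids])
    nd <- normalized_density(obs, null)
    c(nd$nd, nd$p_enrich)
  }
  lko <- leave_k_out(genes$gene_id, statistic, rich, iterations = 150,
                     seed = 3)
  expect_lt(lko$p_nd, 0.05)
})
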