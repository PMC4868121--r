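test_that("architecture metrics follow their definitions", {
  m <- architecture_metrics(5, 1000, c(200, 400, 600, 800))
  expect_equal(m$intron_density, 0.004)
  expect_equal(m$mean_intron_size, 500)
  m0 <- architecture_metrics(1, 900)
  expect_equal(m0$intron_density, 0)
  expect_equal(m0$mean_intron_size, 0)
  # all-GCT CDS: fourfold third positions are all T
  m1 <- architecture_metrics(1, 9, cds = paste0("ATG", "GCTGCT"))
  expect_equal(m1$gc4, 0)
})

test_that("quantile binning separates intronless and balances the rest", {
  suppressWarnings(b <- assign_bins(c(0, 0, 0), 48))
  expect_warning(assign_bins(c(0, 0)), "no positive")
  set.seed(6)
  v <- c(rep(0, 10), runif(96, 100, 5000))
  b <- assign_bins(v, 48)
  expect_equal(b$n_bins, 49)
  expect_true(all(b$bin[v == 0] == 0))
  occ <- tabulate(b$bin[v > 0], 48)
  expect_true(all(occ == 2))  # 96 points over 48 bins
  # boundary ties go to the lower bin
  vals <- c(0, 1, 2, 2, 3, 4)
  bt <- assign_bins(vals, 2)
  expect_equal(bt$bin[vals == 2], c(1L, 1L))
})

test_that("the motif-bin matrix pools family-averaged counts", {
  # one gene of 300 bp with exactly one hit of one motif: raw cell 6/300
  set.seed(41)
  motif <- "GAACTG"
  cds <- paste0("ATG", strrep("CCT", 98), "TAA")  # 300 nt
  substr(cds, 103, 108) <- motif  # exactly one hit in a motif-free background
  genes <- data.frame(gene_id = "g1", cds = cds)
  suppressWarnings(bins <- assign_bins(0, 1))  # single intronless point
  mat <- motif_bin_matrix(genes, c(motif, "AAAAAA"), bins, n_controls = 12)
  expect_equal(mat$raw[1, motif], 6 / 300)
  # motif absent but simulant median positive -> cell -1
  genes2 <- data.frame(gene_id = c("g1", "g2"),
                       cds = c(cds, paste0("ATG", strrep("GAA", 97), "TAA")))
  fam <- data.frame(gene_id = c("g1", "g2"), family_id = c("f1", "f2"))
  suppressWarnings(bins2 <- assign_bins(c(0, 0), 1))
  mat2 <- motif_bin_matrix(genes2, c("GAAGAA", motif), bins2,
                           families = fam, n_controls = 12)
  expect_true(mat2$raw[1, "GAAGAA"] > 0)
  # row sums of per-motif raw cells are bounded below by the union density
  expect_gte(sum(mat2$raw[1, ]),
             ese_density(data.frame(
               gene_id = c("g1", "g2"),
               covered = vapply(genes2$cds, function(s)
                 find_hits(s, c("GAAGAA", motif))$covered, integer(1)),
               length = nchar(genes2$cds)), mode = "pooled") *
               0.999)
})

test_that("non-overlapping motifs make row sums equal the pooled density", {
  cds <- paste0("ATG", "GAACTGAAA", "CCTCCTCCT", "TAA")
  genes <- data.frame(gene_id = "g", cds = cds)
  motifs <- c("GAACTG", "CCTCCT")
  suppressWarnings(bins <- assign_bins(0, 1))
  mat <- motif_bin_matrix(genes, motifs, bins, n_controls = 5)
  union_d <- find_hits(cds, motifs)$covered / nchar(cds)
  expect_equal(sum(mat$raw[1, ]), union_d)
})

test_that("trend classification recovers constructed structure", {
  nd <- cbind(up = 0:9 + rnorm(10, 0, 0.05),
              flat = rnorm(10, 0, 0.05),
              down = 9:0 + rnorm(10, 0, 0.05),
              const = rep(1, 10))
  set.seed(15)
  nd <- nd[, c(1, 2, 3, 4)]
  res <- motif_trend_tests(list(normalized = nd))
  expect_equal(res$class[res$motif == "up"], "positive")
  expect_equal(res$class[res$motif == "down"], "negative")
  expect_equal(res$class[res$motif == "const"], "nonsignificant")
  expect_equal(sum(table(res$class)), 4)
  expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))
})

test_that("flank-planted subsets show inflated flank/core ratios", {
  set.seed(52)
  motifs <- int3_like_motifs()
  subA <- motifs[1:8]   # surplus near window starts plus a uniform trickle
  subB <- motifs[9:16]  # uniform only
  mk_exon <- function() {
    e <- random_sense_cds(80)  # 240 nt
    for (m in sample(subA, 3)) e <- insert_motif(e, m, 1, from = 1, to = 60)
    e <- insert_motif(e, sample(subA, 1), 1)
    for (m in sample(subB, 2)) e <- insert_motif(e, m, 1)
    e
  }
  windows <- lapply(1:60, function(i) exon_windows(mk_exon(), 0))
  fc <- flank_core_contrast(windows, list(A = subA, B = subB),
                            n_control_sets = 200, seed = 9)
  expect_gt(fc$A$flank_nd, fc$A$core_nd)
  expect_gt(fc$A$fold_ratio, fc$B$fold_ratio)
  expect_lt(fc$p_diff, 0.05)
})
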