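# brute-force scan oracle: mark every position under every exact match
brute_mask <- function(seq, motifs) {
  L <- nchar(seq)
  mask <- logical(L)
  for (m in unique(motifs)) {
    w <- nchar(m)
    for (s in seq_len(max(0, L - w + 1)))
      if (substr(seq, s, s + w - 1) == m) mask[s:(s + w - 1)] <- TRUE
  }
  mask
}

test_that("hit scanning matches a brute-force oracle", {
  p <- find_hits("GAAGAAGAA", "GAAGAA")
  expect_equal(sort(p$hit_starts[["GAAGAA"]]), c(0L, 3L))
  expect_equal(p$covered, 9L)
  p2 <- find_hits("TTGAAGAATT", "GAAGAA")
  expect_equal(p2$covered / p2$length, 0.6)
  expect_equal(find_hits("ACGTACGTACGT", "GGGGGG")$covered, 0L)
  set.seed(5)
  motifs <- int3_like_motifs()[1:30]
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                        prob = c(.35, .15, .3, .2)), collapse = "")
    p <- find_hits(seq, motifs)
    expect_equal(p$coverage, brute_mask(seq, motifs))
    # overlaps counted once: union never exceeds the per-motif sum
    expect_lte(p$covered, sum(p$per_motif_counts))
    # every reported start really spells the motif
    for (m in names(p$hit_starts))
      for (s in p$hit_starts[[m]])
        expect_equal(substr(seq, s + 1, s + 6), m)
  }
})

test_that("densities follow per-gene, family-mean and pooled definitions", {
  df <- data.frame(gene_id = c("a", "b"), covered = c(10, 30),
                   length = c(100, 100))
  expect_equal(ese_density(df, mode = "pooled"), 0.2)
  pg <- ese_density(df, mode = "per_gene")
  expect_equal(pg$density, c(0.1, 0.3))
  fam <- data.frame(gene_id = c("a", "b"), family_id = c("F1", "F1"))
  fm <- ese_density(df, families = fam, mode = "family_mean")
  expect_equal(fm$density, 0.2)
  fam2 <- data.frame(gene_id = c("a", "b"), family_id = c("F1", "F2"))
  fm2 <- ese_density(df, families = fam2, mode = "family_mean")
  expect_equal(sort(fm2$density), c(0.1, 0.3))
  expect_error(ese_density(data.frame(gene_id = "a", covered = 0,
                                      length = 0)), "zero-length")
  # pooled density lies between the per-gene extremes
  expect_true(ese_density(df, mode = "pooled") >= min(pg$density) &&
              ese_density(df, mode = "pooled") <= max(pg$density))
})

test_that("exon windows obey the 211-bp filter and the n vs n+3 rule", {
  set.seed(9)
  mk <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
  expect_error(exon_windows(mk(210), 0), "211")
  # 213 nt in frame: flanks are codons 0-22 and 48-70, core 24-46 (0-based)
  e <- mk(213)
  w <- exon_windows(e, 0)
  expect_equal(unname(w$offsets), c(0, 72, 144))
  expect_equal(w$upstream, substr(e, 1, 69))
  expect_equal(w$core, substr(e, 73, 141))
  expect_equal(w$downstream, substr(e, 145, 213))
  # all frames, many lengths: windows are 69 bp, codon aligned, ordered
  # and disjoint, and slicing reconstructs them
  for (L in c(211, 212, 214, 230, 300)) for (fo in 0:2) {
    e <- mk(L)
    w <- exon_windows(e, fo)
    off <- w$offsets
    expect_true(all(nchar(c(w$upstream, w$core, w$downstream)) == 69))
    expect_true(all((off - (3 - fo) %% 3) %% 3 == 0))
    expect_true(off["upstream"] + 69 <= off["core"] &&
                off["core"] + 69 <= off["downstream"])
    expect_equal(w$core, substr(e, off["core"] + 1, off["core"] + 69))
  }
})

test_that("re-scanning a window equals slicing the full mask", {
  set.seed(21)
  motifs <- int3_like_motifs()
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                      prob = c(.3, .2, .3, .2)), collapse = "")
  full <- find_hits(seq, motifs)$coverage
  win <- substr(seq, 101, 300)
  inner <- find_hits(win, motifs)$coverage
  # positions covered by hits lying entirely inside the window agree
  sliced <- brute_mask(win, motifs)
  expect_equal(inner, sliced)
  expect_true(all(full[101:300][inner] | !inner[inner]))
})

test_that("batch window extraction filters and logs rejections", {
  set.seed(2)
  mk <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
  exons <- data.frame(gene_id = c("g1", "g2", "nebulin_like"),
                      seq = c(mk(250), mk(150), mk(250)),
                      frame_offset = c(0L, 1L, 0L))
  res <- window_exons(exons, exclude = "nebulin_like")
  expect_equal(names(res$windows), "g1")
  expect_setequal(res$rejected$reason, c("too_short", "excluded_gene"))
})
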