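# Gene-architecture analyses: per-gene metrics, mean-intron-size quantile
# binning, the bins x motifs pooled-density matrix normalized against
# per-motif dinucleotide permutation controls, rank-trend classification of
# motifs, and the exon flank vs core positional contrast.

#' Architecture metrics of a gene
#'
#' Intron density is (exon count - 1) per bp of CDS, a measure combining
#' exon number and CDS length; mean intron size is 0 for intronless genes.
#'
#' @param exon_count Number of exons.
#' @param cds_length CDS length in bp.
#' @param intron_lengths Numeric vector of intron lengths (possibly empty).
#' @param cds Optional CDS string; enables GC4.
#' @return List with \code{intron_density}, \code{mean_intron_size},
#'   \code{exon_count} and (when \code{cds} is given) \code{gc4}.
#' @export
architecture_metrics <- function(exon_count, cds_length,
                                 intron_lengths = numeric(0), cds = NULL) {
  stopifnot(exon_count >= 1, cds_length > 0)
  out <- list(
    intron_density = (exon_count - 1) / cds_length,
    mean_intron_size = if (length(intron_lengths) == 0) 0
                       else mean(intron_lengths),
    exon_count = exon_count)
  if (!is.null(cds)) out$gc4 <- gc4_content(cds)
  out
}

#' Assign data points to mean-intron-size bins
#'
#' Intronless data points (value 0) form bin 0; positive values are cut at
#' every 1/n-th quantile into n further bins, giving n + 1 bins in total
#' (49 with the default of 48). Values tied with a boundary go to the
#' lower bin, which makes the assignment deterministic and order
#' independent.
#'
#' @param values Nonnegative numeric vector (mean intron size per data
#'   point).
#' @param n_quantile_bins Number of quantile bins for the positive values.
#' @return List with \code{bin} (integer 0..n per data point),
#'   \code{boundaries} (quantile cut values) and \code{n_bins}.
#' @export
assign_bins <- function(values, n_quantile_bins = 48) {
  stopifnot(all(values >= 0))
  bin <- integer(length(values))
  pos <- values > 0
  if (!any(pos)) {
    warning("no positive values: single intronless bin")
    return(list(bin = bin, boundaries = numeric(0), n_bins = 1L))
  }
  n <- n_quantile_bins
  bounds <- stats::quantile(values[pos], probs = seq_len(n - 1) / n,
                            names = FALSE, type = 7)
  v <- values[pos]
  bin[pos] <- vapply(v, function(x) sum(x > bounds), integer(1)) + 1L
  list(bin = bin, boundaries = bounds, n_bins = n + 1L)
}

#' Binned per-motif density matrix with permutation-control normalization
#'
#' Builds the bins x motifs matrix of pooled densities: per-gene per-motif
#' overlapping base counts (a motif's own overlaps merged) are averaged
#' within paralogous families, then summed within each bin and divided by
#' the summed (family-averaged) CDS lengths. Each motif's dinucleotide
#' permutation controls (\code{\link{permutation_controls}}, recycled to
#' \code{n_controls} simulated versions) are pushed through the same
#' pipeline; the per-cell normalized value is
#' (raw - simulant median)/simulant median, with cells whose simulant
#' median is 0 left \code{NA} rather than infinite.
#'
#' @param genes Data frame with \code{gene_id}, \code{cds}.
#' @param motifs Motif set (matrix columns).
#' @param bins Result of \code{\link{assign_bins}} for the data points, in
#'   family order (or gene order when \code{families} is NULL).
#' @param families Optional family table (\code{gene_id},
#'   \code{family_id}); data points are families when given. Bin i of
#'   \code{bins$bin} must then correspond to the i-th family in
#'   \code{sort(unique(family_id))} order.
#' @param n_controls Number of simulated motif-set versions (default 60).
#' @return List of matrices \code{raw}, \code{normalized},
#'   \code{simulant_median} (rows = bins 0.., columns = motifs), plus
#'   \code{control_overlap}: per motif, the fraction of its permutation
#'   controls that are themselves members of the real set (a diagnostic
#'   for normalization bias).
#' @export
motif_bin_matrix <- function(genes, motifs, bins, families = NULL,
                             n_controls = 60) {
  motifs <- as.character(motifs)
  .check_motifs(motifs)
  idxs <- lapply(genes$cds, hit_index)
  lens <- nchar(genes$cds)
  if (is.null(families))
    families <- data.frame(gene_id = genes$gene_id,
                           family_id = genes$gene_id)
  fam_ids <- sort(unique(families$family_id))
  stopifnot(length(bins$bin) == length(fam_ids))
  gene_rows <- match(families$gene_id, genes$gene_id)
  fam_of_gene <- split(gene_rows, families$family_id)[fam_ids]
  fam_len <- vapply(fam_of_gene, function(rows) mean(lens[rows]), numeric(1))
  B <- bins$n_bins
  bin_of_fam <- bins$bin + 1L  # 1-based rows
  len_by_bin <- vapply(seq_len(B), function(b)
    sum(fam_len[bin_of_fam == b]), numeric(1))

  motif_counts <- function(m) {
    cnt <- vapply(idxs, function(ix) {
      s <- ix[[m]]
      if (is.null(s)) 0 else .covered_bases(.merge_hit_runs(s))
    }, numeric(1))
    fam_cnt <- vapply(fam_of_gene, function(rows) mean(cnt[rows]),
                      numeric(1))
    vapply(seq_len(B), function(b)
      sum(fam_cnt[bin_of_fam == b]), numeric(1))
  }
  density_col <- function(m) {
    d <- motif_counts(m) / len_by_bin
    d[len_by_bin == 0] <- NA_real_
    d
  }

  M <- length(motifs)
  raw <- matrix(NA_real_, B, M, dimnames = list(seq_len(B) - 1L, motifs))
  nd <- raw
  med <- raw
  overlap <- setNames(numeric(M), motifs)
  for (j in seq_len(M)) {
    raw[, j] <- density_col(motifs[j])
    ctrl <- permutation_controls(motifs[j])
    overlap[j] <- mean(ctrl %in% motifs)
    ctrl <- rep(ctrl, length.out = n_controls)
    sim <- matrix(vapply(ctrl, density_col, numeric(B)), nrow = B)
    med[, j] <- apply(sim, 1, stats::median)
    ok <- !is.na(med[, j]) & med[, j] > 0
    nd[ok, j] <- (raw[ok, j] - med[ok, j]) / med[ok, j]
  }
  list(raw = raw, normalized = nd, simulant_median = med,
       control_overlap = overlap, bins = bins)
}

#' Classify per-motif trends across intron-size bins
#'
#' Correlates each column of the normalized bins x motifs matrix with the
#' bin indices 0..B-1 (Spearman rank correlation), Holm-adjusts the
#' p-values across motifs, and labels each motif positive, negative or
#' nonsignificant by the sign of the coefficient and the adjusted
#' significance.
#'
#' @param matrix_result Result of \code{\link{motif_bin_matrix}} (or any
#'   list with a \code{normalized} matrix).
#' @param alpha Significance level on the adjusted p-values.
#' @return Data frame with one row per motif: \code{motif},
#'   \code{statistic}, \code{p_raw}, \code{p_adjusted}, \code{class}.
#' @export
motif_trend_tests <- function(matrix_result, alpha = 0.05) {
  nd <- matrix_result$normalized
  B <- nrow(nd)
  stopifnot(B >= 3)
  bin_idx <- seq_len(B) - 1
  res <- lapply(colnames(nd), function(m) {
    col <- nd[, m]
    ok <- !is.na(col)
    if (sum(ok) < 3 || stats::sd(col[ok]) == 0)
      return(data.frame(motif = m, statistic = NA_real_, p_raw = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(col[ok], bin_idx[ok], method = "spearman",
                      exact = FALSE))
    data.frame(motif = m, statistic = unname(ct$estimate),
               p_raw = ct$p.value)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- holm_adjust(res$p_raw)
  res$class <- ifelse(
    is.na(res$p_adjusted) | res$p_adjusted >= alpha, "nonsignificant",
    ifelse(res$statistic > 0, "positive", "negative"))
  res
}

#' Flank versus core motif enrichment contrast
#'
#' For each motif subset, pools upstream-flank windows and core windows
#' separately (summed covered bases over summed window lengths, suited to
#' short sequences where per-gene medians would be 0), normalizes each
#' against dinucleotide-matched control sets drawn from the subset's own
#' pool, and reports the flank/core ratio of fold enrichments. The
#' significance of the ratio difference between the two subsets is an
#' empirical one-tailed p against the same control sets, using the
#' fold-enrichment ratio (observed/null-mean in flanks over the same in
#' cores), which stays stable where the additive ND of a control set is
#' near 0.
#'
#' @param windows List of \code{\link{exon_windows}} results.
#' @param subsets List of two motif sets, e.g. from
#'   \code{\link{split_motifs}} (names kept in the output).
#' @param n_control_sets Control sets per subset.
#' @param seed Optional integer seed.
#' @return List with per-subset results (\code{flank_nd}, \code{core_nd},
#'   \code{ratio} = flank ND/core ND, \code{fold_ratio}) and \code{p_diff},
#'   the one-tailed empirical p that subset 1's fold ratio exceeds subset
#'   2's by the observed margin.
#' @export
flank_core_contrast <- function(windows, subsets, n_control_sets = 1000,
                                seed = NULL) {
  stopifnot(length(subsets) == 2, length(windows) > 0)
  flanks <- vapply(windows, function(w) w$upstream, character(1))
  cores <- vapply(windows, function(w) w$core, character(1))
  fl_idx <- lapply(flanks, hit_index)
  co_idx <- lapply(cores, hit_index)
  fl_len <- sum(nchar(flanks))
  co_len <- sum(nchar(cores))
  pooled <- function(idxs, set, total)
    sum(vapply(idxs, function(ix)
      .covered_bases(.merge_hit_runs(.starts_for_set(ix, set))),
      numeric(1))) / total

  eval_subset <- function(set, sub_seed) {
    ctrl <- build_control_sets(set, n_control_sets, seed = sub_seed)
    obs_f <- pooled(fl_idx, set, fl_len)
    obs_c <- pooled(co_idx, set, co_len)
    null_f <- vapply(ctrl, pooled, numeric(1), idxs = fl_idx, total = fl_len)
    null_c <- vapply(ctrl, pooled, numeric(1), idxs = co_idx, total = co_len)
    mu_f <- mean(null_f); mu_c <- mean(null_c)
    nd_f <- if (mu_f > 0) (obs_f - mu_f) / mu_f else NA_real_
    nd_c <- if (mu_c > 0) (obs_c - mu_c) / mu_c else NA_real_
    list(flank_nd = nd_f, core_nd = nd_c,
         ratio = if (!is.na(nd_c) && nd_c > 0) nd_f / nd_c else NA_real_,
         fold_ratio = if (mu_f > 0 && mu_c > 0 && obs_c > 0)
           (obs_f / mu_f) / (obs_c / mu_c) else NA_real_,
         null_fold_ratio = ifelse(null_c > 0 & mu_f > 0 & mu_c > 0,
                                  (null_f / mu_f) / (null_c / mu_c),
                                  NA_real_))
  }
  s1 <- eval_subset(as.character(subsets[[1]]),
                    if (is.null(seed)) NULL else substream_seed(seed, "fc1"))
  s2 <- eval_subset(as.character(subsets[[2]]),
                    if (is.null(seed)) NULL else substream_seed(seed, "fc2"))
  obs_diff <- s1$fold_ratio - s2$fold_ratio
  null_diff <- s1$null_fold_ratio - s2$null_fold_ratio
  p_diff <- if (is.na(obs_diff)) NA_real_ else
    empirical_p(obs_diff, null_diff, "greater")$p
  out <- list(subset1 = s1[c("flank_nd", "core_nd", "ratio", "fold_ratio")],
              subset2 = s2[c("flank_nd", "core_nd", "ratio", "fold_ratio")],
              p_diff = p_diff)
  if (!is.null(names(subsets))) names(out)[1:2] <- names(subsets)
  out
}
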