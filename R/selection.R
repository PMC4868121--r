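# Selection tests inside motif regions: codon-repaired block extraction,
# concatenated dS against dinucleotide-matched control motif sets, and
# SNP density / low-MAF fraction statistics.
#
# The block repair rule: each contiguous run of motif-covered bases is made
# codon-complete by trimming an incomplete final codon and expanding an
# incomplete initial codon with 1-2 upstream bases. If the completed
# initial codon encodes Leu or Arg (the only amino acids with first-
# position degeneracy), its first two bases are rewritten to GA when the
# third base is 2-fold degenerate and GC when 4-fold, in both rows. This
# keeps the block's motif-internal synonymous site while preventing the
# expansion from importing a non-motif synonymous site at position 1.

.LEU_ARG <- c("L", "R")

.repair_prefix <- function(codon) {
  deg3 <- .degeneracy_table()[codon, 3]
  if (deg3 == 2) "GA" else "GC"
}

# Per-alignment index used by the concatenated-dS engine: per focal codon
# the ortholog codon (via alignment columns), NG86 counts and their
# cumulative sums (invalid columns contribute 0), and repair metadata.
ds_index <- function(focal, ortholog) {
  f <- strsplit(focal, "", fixed = TRUE)[[1]]
  o <- strsplit(ortholog, "", fixed = TRUE)[[1]]
  if (length(f) != length(o)) stop("rows must have equal aligned length")
  cols <- which(f != "-")
  if (length(cols) %% 3 != 0) stop("ungapped focal length not a multiple of 3")
  n <- length(cols) %/% 3
  dim(cols) <- NULL
  m <- matrix(cols, nrow = 3)
  fc <- vapply(seq_len(n), function(i) paste(f[m[, i]], collapse = ""),
               character(1))
  oc <- vapply(seq_len(n), function(i) paste(o[m[, i]], collapse = ""),
               character(1))
  cnt <- .ng86_codon_counts(fc, oc)
  valid <- !is.na(cnt$S)
  z <- function(v) { v[!valid] <- 0; cumsum(v) }
  aa <- .codon_aa()
  list(fc = fc, oc = oc, n_codons = n, L = 3L * n,
       valid = valid,
       cS = z(cnt$S), cN = z(cnt$N), cSd = z(cnt$Sd), cNd = z(cnt$Nd),
       aa = unname(aa[fc]),
       focal_ungapped = paste(f[cols], collapse = ""))
}

# Summed NG86 counts over codon-repaired blocks defined by 1-based
# inclusive runs on the focal CDS.
.run_counts <- function(dsi, runs) {
  tot <- c(S = 0, N = 0, Sd = 0, Nd = 0)
  if (nrow(runs) == 0) return(tot)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1]; b <- runs[r, 2]
    c1 <- ((a - 1L) %/% 3L) + 1L
    c2 <- b %/% 3L
    if (c2 < c1) next
    rng <- function(cv) cv[c2] - if (c1 > 1) cv[c1 - 1] else 0
    S <- rng(dsi$cS); N <- rng(dsi$cN)
    Sd <- rng(dsi$cSd); Nd <- rng(dsi$cNd)
    if ((a - 1L) %% 3L != 0L && dsi$valid[c1] &&
        dsi$aa[c1] %in% .LEU_ARG) {
      pre <- .repair_prefix(dsi$fc[c1])
      frep <- paste0(pre, substr(dsi$fc[c1], 3, 3))
      orep <- paste0(pre, substr(dsi$oc[c1], 3, 3))
      new <- .ng86_codon_counts(frep, orep)
      if (!is.na(new$S)) {
        old <- .ng86_codon_counts(dsi$fc[c1], dsi$oc[c1])
        S <- S - old$S + new$S; N <- N - old$N + new$N
        Sd <- Sd - old$Sd + new$Sd; Nd <- Nd - old$Nd + new$Nd
      }
    }
    tot <- tot + c(S, N, Sd, Nd)
  }
  tot
}

#' Extract codon-complete motif blocks from a pairwise alignment
#'
#' Converts each contiguous run of motif-covered bases into a
#' codon-complete block of the alignment, applying the repair rule
#' described for \code{\link{concatenated_ds}}: incomplete final codons
#' are trimmed, incomplete initial codons are expanded 1-2 bases upstream,
#' and expanded initial Leu/Arg codons are rewritten to GA/GC (by third-
#' base degeneracy) in both rows, except where the ortholog codon carries
#' an indel.
#'
#' @param focal,ortholog Codon-aligned rows (gaps \code{-} allowed in the
#'   ortholog; focal gaps are skipped); motif coordinates refer to the
#'   ungapped focal row.
#' @param mask Logical vector over ungapped focal positions (e.g. the
#'   \code{coverage} component of \code{\link{find_hits}}).
#' @return List with \code{blocks} (each a list \code{focal},
#'   \code{ortholog}, \code{start} -- the 0-based focal CDS position of
#'   the block -- and \code{repaired}) and \code{repaired_positions},
#'   0-based focal positions whose bases were rewritten.
#' @export
extract_ese_blocks <- function(focal, ortholog, mask) {
  dsi <- ds_index(focal, ortholog)
  if (length(mask) != dsi$L)
    stop("mask length must equal ungapped focal length")
  runs <- .logical_runs(mask)
  blocks <- list()
  repaired <- integer(0)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1]; b <- runs[r, 2]
    c1 <- ((a - 1L) %/% 3L) + 1L
    c2 <- b %/% 3L
    if (c2 < c1) next
    fcod <- dsi$fc[c1:c2]
    ocod <- dsi$oc[c1:c2]
    rep_flag <- FALSE
    if ((a - 1L) %% 3L != 0L && dsi$aa[c1] %in% .LEU_ARG) {
      pre <- .repair_prefix(dsi$fc[c1])
      fcod[1] <- paste0(pre, substr(fcod[1], 3, 3))
      if (!grepl("-", ocod[1])) ocod[1] <- paste0(pre, substr(ocod[1], 3, 3))
      rep_flag <- TRUE
      repaired <- c(repaired, (c1 - 1L) * 3L + 0:1)
    }
    blocks[[length(blocks) + 1]] <- list(
      focal = paste(fcod, collapse = ""),
      ortholog = paste(ocod, collapse = ""),
      start = (c1 - 1L) * 3L,
      repaired = rep_flag)
  }
  list(blocks = blocks, repaired_positions = repaired)
}

# 1-based inclusive runs of TRUE in a logical vector.
.logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

.coverage_logical <- function(runs, L) {
  cov <- logical(L)
  if (nrow(runs) > 0)
    cov[unlist(mapply(seq.int, runs[, 1], runs[, 2], SIMPLIFY = FALSE))] <- TRUE
  cov
}

#' Concatenated synonymous rate within motif regions
#'
#' For each alignment, motif hits are located on the (ungapped) focal row,
#' covered runs are made codon-complete (see
#' \code{\link{extract_ese_blocks}}), and NG86 counts are summed over the
#' concatenation of all blocks across all alignments; a single dS is then
#' computed from the pooled counts, which makes the result invariant to
#' concatenation order. The same procedure applied to each control motif
#' set yields the null distribution; the normalized dS is
#' (observed - null mean)/null mean and the empirical p is one-tailed for
#' a reduction.
#'
#' @param alignments Named list; each element a list with \code{focal} and
#'   \code{ortholog} codon-aligned rows.
#' @param motifs Character vector: the real motif set.
#' @param control_sets Optional list of control motif sets (e.g. from
#'   \code{\link{build_control_sets}}).
#' @return List with \code{observed_ds}, \code{counts}, and when controls
#'   are given \code{null_ds}, \code{normalized_ds}, \code{p} (class
#'   \code{ds_result}).
#' @export
concatenated_ds <- function(alignments, motifs, control_sets = NULL) {
  if (length(alignments) == 0) stop("no alignments supplied")
  motifs <- as.character(motifs)
  idxs <- lapply(alignments, function(a) {
    dsi <- ds_index(a$focal, a$ortholog)
    dsi$scan <- hit_index(dsi$focal_ungapped)
    dsi
  })
  set_counts <- function(set) {
    tot <- c(S = 0, N = 0, Sd = 0, Nd = 0)
    for (dsi in idxs) {
      starts <- .starts_for_set(dsi$scan, set)
      runs <- .merge_hit_runs(starts)
      tot <- tot + .run_counts(dsi, runs)
    }
    tot
  }
  obs <- set_counts(motifs)
  if (obs["S"] == 0) stop("empty concatenation: no countable motif blocks")
  obs_rates <- .rates_from_counts(obs["S"], obs["N"], obs["Sd"], obs["Nd"])
  out <- list(observed_ds = obs_rates$ds, counts = obs)
  if (!is.null(control_sets)) {
    null_ds <- vapply(control_sets, function(set) {
      cnt <- set_counts(set)
      if (cnt["S"] == 0) return(NA_real_)
      .rates_from_counts(cnt["S"], cnt["N"], cnt["Sd"], cnt["Nd"])$ds
    }, numeric(1))
    mu <- mean(null_ds, na.rm = TRUE)
    out$null_ds <- null_ds
    out$normalized_ds <- if (is.finite(mu) && mu > 0)
      (obs_rates$ds - mu) / mu else NA_real_
    out$p <- empirical_p(obs_rates$ds, null_ds, "less")$p
  }
  structure(out, class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat(sprintf("concatenated dS in motif regions: %.4g", x$observed_ds))
  if (!is.null(x$null_ds))
    cat(sprintf(" (null mean %.4g, normalized %.4g, one-tailed p = %.4g)",
                mean(x$null_ds, na.rm = TRUE), x$normalized_ds, x$p))
  cat("\n")
  invisible(x)
}

#' SNP density and low-MAF fraction inside motif regions
#'
#' SNP density at fourfold degenerate sites is the number of SNPs at
#' 4-fold sites inside motif coverage divided by the number of 4-fold
#' sites inside coverage; both a synonymous-only and an all-SNP numerator
#' are reported. The low-MAF fraction is the share of motif-covered
#' segregating sites with minor allele frequency below
#' \code{maf_threshold}, over all SNPs. When a family table is given, each
#' replicate redraws one random member per family (reproducible named
#' substreams) and the medians of the statistics and of the empirical
#' p-values over replicates are reported.
#'
#' @param genes Data frame with columns \code{gene_id}, \code{cds}.
#' @param snps Data frame with columns \code{gene_id}, \code{cds_pos}
#'   (0-based), \code{maf} and \code{consequence} (\code{"synonymous"} or
#'   \code{"nonsynonymous"}).
#' @param motifs Real motif set.
#' @param control_sets Optional list of control motif sets; enables
#'   empirical p-values (density: one-tailed reduction; low-MAF fraction:
#'   one-tailed excess).
#' @param families Optional data frame (\code{gene_id}, \code{family_id}).
#' @param maf_threshold Low-MAF cutoff (default 1/2000).
#' @param n_replicates Family-representative redraws.
#' @param seed Optional integer seed.
#' @return List with \code{replicates} (one row per replicate) and the
#'   medians \code{snp_density_4d}, \code{snp_density_4d_all},
#'   \code{low_maf_fraction}, plus \code{p_density}, \code{p_low_maf}
#'   when controls are supplied.
#' @export
snp_statistics <- function(genes, snps, motifs, control_sets = NULL,
                           families = NULL, maf_threshold = 1 / 2000,
                           n_replicates = 10, seed = NULL) {
  stopifnot(nrow(genes) >= 1)
  motifs <- as.character(motifs)
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    cds <- genes$cds[i]
    gs <- snps[snps$gene_id == genes$gene_id[i], , drop = FALSE]
    if (any(gs$cds_pos < 0 | gs$cds_pos >= nchar(cds)))
      stop("SNP position outside CDS for gene ", genes$gene_id[i])
    list(idx = hit_index(cds),
         L = nchar(cds),
         fold4 = annotate_degeneracy(cds) == 4L,
         pos = gs$cds_pos + 1L,
         syn = gs$consequence == "synonymous",
         low = gs$maf < maf_threshold)
  })
  names(per_gene) <- genes$gene_id
  if (is.null(families))
    families <- data.frame(gene_id = genes$gene_id,
                           family_id = genes$gene_id)
  fam_members <- split(families$gene_id, families$family_id)
  singleton <- all(lengths(fam_members) == 1)
  if (singleton) n_replicates <- 1L

  stats_for <- function(ids, set) {
    n4 <- 0; s4_syn <- 0; s4_all <- 0; in_mask <- 0; low <- 0
    for (id in ids) {
      g <- per_gene[[id]]
      runs <- .merge_hit_runs(.starts_for_set(g$idx, set))
      cov <- .coverage_logical(runs, g$L)
      n4 <- n4 + sum(cov & g$fold4)
      snp_in <- cov[g$pos]
      s4 <- snp_in & g$fold4[g$pos]
      s4_syn <- s4_syn + sum(s4 & g$syn)
      s4_all <- s4_all + sum(s4)
      in_mask <- in_mask + sum(snp_in)
      low <- low + sum(snp_in & g$low)
    }
    c(density = if (n4 > 0) s4_syn / n4 else NA_real_,
      density_all = if (n4 > 0) s4_all / n4 else NA_real_,
      low_maf = if (in_mask > 0) low / in_mask else NA_real_)
  }

  reps <- lapply(seq_len(n_replicates), function(r) {
    ids <- .with_seed(
      if (is.null(seed)) NULL else substream_seed(seed, paste0("snp_rep", r)),
      vapply(fam_members, function(m)
        if (length(m) == 1) m else sample(m, 1), character(1)))
    obs <- stats_for(ids, motifs)
    row <- as.list(obs)
    if (!is.null(control_sets)) {
      null <- t(vapply(control_sets, function(s) stats_for(ids, s),
                       numeric(3)))
      row$p_density <- if (is.na(obs["density"])) NA_real_ else
        empirical_p(obs["density"], null[, "density"], "less")$p
      row$p_low_maf <- if (is.na(obs["low_maf"])) NA_real_ else
        empirical_p(obs["low_maf"], null[, "low_maf"], "greater")$p
    }
    as.data.frame(row)
  })
  reps <- do.call(rbind, reps)
  med <- function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE)
  out <- list(replicates = reps,
              snp_density_4d = med(reps$density),
              snp_density_4d_all = med(reps$density_all),
              low_maf_fraction = med(reps$low_maf))
  if (!is.null(control_sets)) {
    out$p_density <- med(reps$p_density)
    out$p_low_maf <- med(reps$p_low_maf)
  }
  out
}
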