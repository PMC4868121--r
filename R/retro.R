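# Retrocopy analyses: broad overlap-based calls, strict parent matching by
# dN, ancestral exon-junction mapping, and leave-k-out resampling to gauge
# how much retrocopies contribute to an enrichment signal.

#' Broad retrocopy calls from interval overlap
#'
#' A gene is a broad-set retrocopy when at least \code{min_fraction} of
#' its span is overlapped by the union of retrocopy annotation intervals.
#' Intervals are 0-based half-open on a shared coordinate system.
#'
#' @param gene_intervals Data frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param retro_intervals Data frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @param min_fraction Overlap threshold (inclusive).
#' @return Data frame with \code{gene_id}, \code{overlap_fraction} and
#'   \code{tier} (\code{"broad"} or \code{"none"}).
#' @export
broad_retrocopy_calls <- function(gene_intervals, retro_intervals,
                                  min_fraction = 0.5) {
  g <- gene_intervals
  r <- retro_intervals
  if (any(g$start < 0) || any(g$end <= g$start) ||
      (nrow(r) > 0 && (any(r$start < 0) || any(r$end <= r$start))))
    stop("malformed intervals: need 0 <= start < end")
  frac <- vapply(seq_len(nrow(g)), function(i) {
    ri <- r[r$chrom == g$chrom[i], , drop = FALSE]
    if (nrow(ri) == 0) return(0)
    red <- IRanges::reduce(IRanges::IRanges(ri$start + 1L, ri$end))
    ov <- IRanges::intersect(IRanges::IRanges(g$start[i] + 1L, g$end[i]), red)
    sum(IRanges::width(ov)) / (g$end[i] - g$start[i])
  }, numeric(1))
  data.frame(gene_id = g$gene_id, overlap_fraction = frac,
             tier = ifelse(frac >= min_fraction, "broad", "none"))
}

#' Match a retrocopy to its parent gene by dN
#'
#' Candidate parents failing the length-ratio rule (shorter CDS must be
#' over half the longer) or CDS validation (translatability) are dropped;
#' the rest are protein-aligned and back-threaded to codons, and dN is
#' computed. The call is strict when the minimum dN is below
#' \code{dn_threshold}; the parent is the argmin-dN candidate, ties going
#' to the lexicographically smaller id.
#'
#' @param retrocopy List with \code{gene_id} and \code{cds}.
#' @param candidates Data frame with \code{gene_id}, \code{cds}.
#' @param dn_threshold Maximum parental dN (default 0.2).
#' @param min_length_ratio Shorter/longer CDS length minimum (exclusive).
#' @return List with \code{gene_id}, \code{tier} (\code{"strict"} or
#'   \code{"broad"}), \code{parent_id}, \code{parent_dn} and the
#'   per-candidate table \code{candidates}.
#' @export
strict_parent_match <- function(retrocopy, candidates, dn_threshold = 0.2,
                                min_length_ratio = 0.5) {
  res <- data.frame(gene_id = character(0), dn = numeric(0))
  for (i in seq_len(nrow(candidates))) {
    cds <- candidates$cds[i]
    lens <- c(nchar(retrocopy$cds), nchar(cds))
    if (min(lens) / max(lens) <= min_length_ratio) next
    if (nchar(cds) %% 3 != 0 || grepl("[^ACGT]", cds)) next
    cods <- .split_codons(cds)
    if (any(cods[-length(cods)] %in% .STOPS)) next
    aln <- align_codon_pair(retrocopy$cds, cds)
    dn <- tryCatch(pairwise_codon_rates(aln$focal, aln$ortholog)$dn,
                   error = function(e) NA_real_)
    res <- rbind(res, data.frame(gene_id = candidates$gene_id[i], dn = dn))
  }
  res <- res[order(res$dn, res$gene_id), , drop = FALSE]
  hit <- nrow(res) > 0 && !is.na(res$dn[1]) && res$dn[1] < dn_threshold
  list(gene_id = retrocopy$gene_id,
       tier = if (hit) "strict" else "broad",
       parent_id = if (hit) res$gene_id[1] else NA_character_,
       parent_dn = if (hit) res$dn[1] else NA_real_,
       candidates = res)
}

#' Map ancestral exon junctions into a retrocopy and count nearby hits
#'
#' Junctions are the parent-CDS positions of each noninitial exon start.
#' Each is mapped through the codon alignment to the retrocopy; a junction
#' whose 30-bp parent-side probe has less than half of its aligned bases
#' intact (indel-free) is kept among parent junctions but excluded from
#' retrocopy pseudo-junctions. A motif hit is near a junction when the
#' distance from its first base to the junction is at most \code{window}
#' (inclusive).
#'
#' @param parent_exon_cds_starts Integer vector: 0-based parent-CDS start
#'   positions of noninitial exons.
#' @param alignment List with \code{focal} (retrocopy) and
#'   \code{ortholog} (parent) codon-aligned rows.
#' @param hit_starts Integer vector of 0-based motif hit starts on the
#'   retrocopy CDS.
#' @param window Distance cutoff in bp (default 50).
#' @param probe Probe length in bp used for the intactness rule.
#' @return List with \code{junctions_parent}, \code{junctions_retro}
#'   (0-based, only intact ones), \code{intact} flags and
#'   \code{fraction_near}, the share of hits within \code{window} of a
#'   pseudo-junction (\code{NA} with no hits or no junctions).
#' @export
junction_proximity <- function(parent_exon_cds_starts, alignment,
                               hit_starts, window = 50, probe = 30) {
  f <- strsplit(alignment$focal, "", fixed = TRUE)[[1]]
  o <- strsplit(alignment$ortholog, "", fixed = TRUE)[[1]]
  # per alignment column: 0-based coordinates on each ungapped row
  fpos <- cumsum(f != "-") - 1L
  opos <- cumsum(o != "-") - 1L
  n_parent <- sum(o != "-")
  intact <- logical(length(parent_exon_cds_starts))
  retro_j <- rep(NA_integer_, length(parent_exon_cds_starts))
  for (k in seq_along(parent_exon_cds_starts)) {
    j <- parent_exon_cds_starts[k]
    cols <- which(o != "-" & opos >= j & opos < j + probe)
    if (length(cols) == 0) next
    frac_intact <- mean(f[cols] != "-")
    intact[k] <- frac_intact >= 0.5
    anchor <- cols[f[cols] != "-"]
    if (intact[k] && length(anchor) > 0)
      retro_j[k] <- fpos[anchor[1]]
  }
  retro_j_ok <- retro_j[intact & !is.na(retro_j)]
  fraction <- if (length(hit_starts) == 0 || length(retro_j_ok) == 0)
    NA_real_
  else mean(vapply(hit_starts, function(h)
    min(abs(h - retro_j_ok)) <= window, logical(1)))
  list(junctions_parent = parent_exon_cds_starts,
       junctions_retro = retro_j_ok,
       intact = intact,
       fraction_near = fraction)
}

#' Leave-k-out resampling of an enrichment statistic
#'
#' Quantifies whether removing a designated gene set (e.g. the broad
#' retrocopy set) changes an enrichment statistic more than removing k
#' random genes: at each iteration k random genes are dropped and the
#' change in the statistic pair (ND, p) relative to the full set is
#' recorded; the true removal's deltas are then ranked in the resampled
#' distributions.
#'
#' @param gene_ids Character vector of all gene ids.
#' @param statistic Function mapping a character vector of retained gene
#'   ids to a numeric vector \code{c(nd, p)}.
#' @param observed_removal Character vector: the true removal set.
#' @param k Number of genes removed per iteration (default: size of
#'   \code{observed_removal}).
#' @param iterations Number of random removals.
#' @param seed Optional integer seed.
#' @return List with \code{full}, \code{true_delta} (ND and p changes for
#'   the true removal), \code{null_delta} (iterations x 2 matrix),
#'   \code{p_nd} (one-tailed: true ND drop as extreme or more) and
#'   \code{p_p} (one-tailed: true p increase as extreme or more).
#' @export
leave_k_out <- function(gene_ids, statistic, observed_removal,
                        k = length(observed_removal), iterations = 1000,
                        seed = NULL) {
  n <- length(gene_ids)
  if (k >= n) stop("k must be smaller than the number of genes")
  full <- statistic(gene_ids)
  true_stat <- statistic(setdiff(gene_ids, observed_removal))
  true_delta <- true_stat - full
  null_delta <- .with_seed(seed, t(vapply(seq_len(iterations), function(i) {
    keep <- if (k == 0) gene_ids else gene_ids[-sample.int(n, k)]
    statistic(keep) - full
  }, numeric(2))))
  colnames(null_delta) <- c("delta_nd", "delta_p")
  list(full = full,
       true_delta = setNames(true_delta, c("delta_nd", "delta_p")),
       null_delta = null_delta,
       p_nd = empirical_p(true_delta[1], null_delta[, 1], "less")$p,
       p_p = empirical_p(true_delta[2], null_delta[, 2], "greater")$p)
}
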