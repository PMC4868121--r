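# Exact hexamer scanning with union coverage, plus the density summaries
# (per gene, paralog-family mean, pooled) and codon-aligned exon windows.
#
# Internally all coordinates are 0-based half-open; hit starts are reported
# 0-based to match the on-disk BED convention.

# Index of every hexamer occurrence in a sequence: a named list mapping
# hexamer -> sorted 1-based start positions. Built once per gene and reused
# across motif sets (real and the thousands of control sets).
hit_index <- function(seq) {
  L <- nchar(seq)
  if (L < 6) return(structure(list(), length = L))
  starts <- seq_len(L - 5L)
  hex <- substring(seq, starts, starts + 5L)
  idx <- split(starts, hex)
  structure(idx, length = L)
}

# Merge sorted 1-based hit starts (fixed width 6) into runs; returns a
# 2-column matrix of inclusive 1-based [start, end].
.merge_hit_runs <- function(starts, width = 6L) {
  n <- length(starts)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  if (n > 1) {
    brk <- starts[-1] > starts[-n] + width
    grp <- cumsum(c(TRUE, brk))
  } else grp <- 1L
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  cbind(starts[first], starts[last] + width - 1L)
}

.covered_bases <- function(runs) {
  if (nrow(runs) == 0) return(0L)
  sum(runs[, 2] - runs[, 1] + 1L)
}

.starts_for_set <- function(index, motifs) {
  hits <- unlist(index[intersect(motifs, names(index))], use.names = FALSE)
  sort(hits)
}

#' Scan a sequence for motif hits
#'
#' Exhaustive exact matching of a hexamer set at every offset. The
#' coverage mask is the union of all hit intervals, so bases under two or
#' more overlapping motifs are counted once; per-motif counts merge only
#' that motif's own overlaps.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param motifs Character vector of hexamers.
#' @return An object of class \code{hit_profile}: a list with
#'   \code{length}, logical \code{coverage} (one element per position),
#'   \code{covered} (bases under at least one hit), named integer
#'   \code{per_motif_counts}, and \code{hit_starts} (named list of 0-based
#'   start offsets per motif, motifs without hits omitted).
#' @examples
#' find_hits("GAAGAAGAA", "GAAGAA")$covered  # 9: two overlapping hits
#' @export
find_hits <- function(seq, motifs) {
  motifs <- unique(as.character(motifs))  # control sets may carry duplicates
  if (any(nchar(motifs) != 6) || any(grepl("[^ACGT]", motifs)))
    stop("all motifs must be hexamers over A/C/G/T")
  if (grepl("[^ACGT]", seq)) stop("sequence must be over A/C/G/T")
  idx <- hit_index(seq)
  L <- attr(idx, "length")
  starts <- .starts_for_set(idx, motifs)
  runs <- .merge_hit_runs(starts)
  coverage <- logical(L)
  if (nrow(runs) > 0)
    coverage[unlist(mapply(seq.int, runs[, 1], runs[, 2],
                           SIMPLIFY = FALSE))] <- TRUE
  present <- intersect(motifs, names(idx))
  per_motif <- vapply(present, function(m)
    .covered_bases(.merge_hit_runs(idx[[m]])), integer(1))
  counts <- setNames(integer(length(motifs)), motifs)
  counts[present] <- per_motif
  structure(list(length = L,
                 coverage = coverage,
                 covered = .covered_bases(runs),
                 per_motif_counts = counts,
                 hit_starts = lapply(idx[present], function(s) s - 1L)),
            class = "hit_profile")
}

#' @export
print.hit_profile <- function(x, ...) {
  cat("hit_profile:", x$covered, "of", x$length, "bases covered (density",
      signif(x$covered / x$length, 3), ")\n")
  invisible(x)
}

#' Motif density of scanned sequences
#'
#' Density is the proportion of nucleotides that are part of at least one
#' motif hit. Three granularities are supported: per gene
#' (covered/length), paralog-family mean (the arithmetic mean of member
#' densities, so each family contributes one data point), and pooled
#' (summed covered bases over summed lengths).
#'
#' @param profiles A list of \code{hit_profile} objects, named by gene id,
#'   or a data frame with columns \code{gene_id}, \code{covered},
#'   \code{length}.
#' @param families Optional data frame with columns \code{gene_id} and
#'   \code{family_id}; required for \code{mode = "family_mean"}.
#' @param mode One of \code{"per_gene"}, \code{"family_mean"},
#'   \code{"pooled"}.
#' @return For \code{"pooled"}, a single fraction; otherwise a data frame
#'   with one row per gene or family and a \code{density} column.
#' @export
ese_density <- function(profiles, families = NULL,
                        mode = c("per_gene", "family_mean", "pooled")) {
  mode <- match.arg(mode)
  if (is.data.frame(profiles)) {
    df <- profiles
  } else {
    if (length(profiles) == 0) stop("no profiles supplied")
    df <- data.frame(
      gene_id = if (is.null(names(profiles)))
        paste0("g", seq_along(profiles)) else names(profiles),
      covered = vapply(profiles, function(p) as.numeric(p$covered),
                       numeric(1)),
      length = vapply(profiles, function(p) as.numeric(p$length),
                      numeric(1)))
  }
  if (any(df$length <= 0)) stop("zero-length sequence")
  if (mode == "pooled") return(sum(df$covered) / sum(df$length))
  df$density <- df$covered / df$length
  if (mode == "per_gene") return(df[c("gene_id", "density")])
  if (is.null(families)) stop("family_mean mode requires a family table")
  m <- merge(df, families[c("gene_id", "family_id")], by = "gene_id")
  agg <- stats::aggregate(density ~ family_id, data = m, FUN = mean)
  agg
}

#' Extract codon-aligned flank and core windows from an exon
#'
#' Splits a fully coding, internal exon into three nonoverlapping 69-bp
#' codon-aligned windows: an upstream flank (first 69 in-frame bases), a
#' downstream flank (last 69 in-frame bases) and a core. Up to two bases
#' are trimmed at either end to reach codon boundaries, which is why exons
#' shorter than 211 bp (69 x 3 + 2 x 2) are rejected. When the codon gap
#' between the flanks minus 23 codons is even the core sits exactly midway;
#' otherwise it is offset one codon toward the 5' side (a distance of n
#' bases from the upstream flank and n + 3 from the downstream one).
#'
#' @param exon_seq Exon nucleotide string.
#' @param frame_offset 0, 1 or 2: number of bases of the exon's first codon
#'   that belong to the previous exon.
#' @return A list with \code{upstream}, \code{core}, \code{downstream}
#'   (69-bp strings) and \code{offsets}, their 0-based start positions
#'   within the exon.
#' @export
exon_windows <- function(exon_seq, frame_offset = 0) {
  L <- nchar(exon_seq)
  if (L < 211) stop("exon shorter than 211 bp")
  stopifnot(frame_offset %in% 0:2)
  t1 <- (3L - as.integer(frame_offset)) %% 3L
  L1 <- L - t1
  t2 <- L1 %% 3L
  K <- (L1 - t2) %/% 3L          # full codons available
  codon_start <- function(c) t1 + 3L * (c - 1L)  # 0-based
  up_start <- codon_start(1L)
  down_start <- codon_start(K - 22L)
  G <- K - 46L                   # codons between the flanks
  m5 <- if ((G - 23L) %% 2L == 0L) (G - 23L) %/% 2L else (G - 24L) %/% 2L
  core_start <- codon_start(23L + m5 + 1L)
  sub <- function(s0) substr(exon_seq, s0 + 1L, s0 + 69L)
  list(upstream = sub(up_start),
       core = sub(core_start),
       downstream = sub(down_start),
       offsets = c(upstream = up_start, core = core_start,
                   downstream = down_start))
}

#' Batch exon window extraction with filtering
#'
#' Applies \code{\link{exon_windows}} to a table of exons, silently
#' filtering (and reporting) exons shorter than 211 bp and any gene ids on
#' an exclusion list (e.g. genes with many identical exons).
#'
#' @param exons Data frame with columns \code{gene_id}, \code{seq} and
#'   \code{frame_offset}.
#' @param exclude Character vector of gene ids to drop.
#' @return A list with \code{windows} (list of \code{exon_windows}
#'   results, one per retained exon, carrying gene ids as names) and
#'   \code{rejected} (data frame of dropped exons with reasons).
#' @export
window_exons <- function(exons, exclude = character(0)) {
  keep_len <- nchar(exons$seq) >= 211
  keep_gene <- !(exons$gene_id %in% exclude)
  keep <- keep_len & keep_gene
  rejected <- data.frame(
    gene_id = exons$gene_id[!keep],
    reason = ifelse(!keep_gene[!keep], "excluded_gene", "too_short"))
  windows <- mapply(exon_windows, exons$seq[keep], exons$frame_offset[keep],
                    SIMPLIFY = FALSE)
  names(windows) <- exons$gene_id[keep]
  list(windows = windows, rejected = rejected)
}
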