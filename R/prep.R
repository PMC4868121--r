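# CDS validation, protein-level ortholog alignment back-threaded to codons,
# paralog family clustering, and the ortholog divergence filters.

.STOPS <- c("TAA", "TAG", "TGA")

#' Validate a coding sequence
#'
#' A CDS passes when it is at least \code{min_len} bp, a multiple of 3,
#' contains only A/C/G/T, starts with ATG, ends with a stop codon
#' (TAA/TAG/TGA), and contains no in-frame internal stop.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum length in bp.
#' @return List with \code{pass} (logical) and \code{reasons}, a character
#'   vector drawn from \code{too_short}, \code{noncanonical_base},
#'   \code{length_not_multiple_of_3}, \code{no_start},
#'   \code{no_terminal_stop}, \code{premature_stop}. \code{pass} is TRUE
#'   iff \code{reasons} is empty.
#' @export
validate_cds <- function(seq, min_len = 300) {
  if (!nzchar(seq)) stop("empty sequence")
  reasons <- character(0)
  L <- nchar(seq)
  if (L < min_len) reasons <- c(reasons, "too_short")
  if (grepl("[^ACGT]", seq)) reasons <- c(reasons, "noncanonical_base")
  if (L %% 3 != 0) reasons <- c(reasons, "length_not_multiple_of_3")
  if (substr(seq, 1, 3) != "ATG") reasons <- c(reasons, "no_start")
  n_full <- L %/% 3
  if (n_full >= 1) {
    cods <- substring(seq, 3 * seq_len(n_full) - 2, 3 * seq_len(n_full))
    terminal_ok <- L %% 3 == 0 && cods[n_full] %in% .STOPS
    if (!terminal_ok) reasons <- c(reasons, "no_terminal_stop")
    internal <- if (L %% 3 == 0) cods[-n_full] else cods
    if (any(internal %in% .STOPS)) reasons <- c(reasons, "premature_stop")
  } else reasons <- c(reasons, "no_terminal_stop")
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Protein-level global alignment of two CDSs (terminal stops dropped),
# back-threaded to codons. Returns gapped codon-aligned nucleotide rows.
align_codon_pair <- function(cds1, cds2) {
  strip_stop <- function(s) {
    if (nchar(s) %% 3 == 0 && substr(s, nchar(s) - 2, nchar(s)) %in% .STOPS)
      substr(s, 1, nchar(s) - 3) else s
  }
  s1 <- strip_stop(cds1)
  s2 <- strip_stop(cds2)
  p1 <- Biostrings::AAString(translate_cds(s1))
  p2 <- Biostrings::AAString(translate_cds(s2))
  aln <- Biostrings::pairwiseAlignment(
    p1, p2, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cod1 <- .split_codons(s1)
  cod2 <- .split_codons(s2)
  i <- 0; j <- 0
  row1 <- character(length(a1)); row2 <- character(length(a2))
  for (k in seq_along(a1)) {
    if (a1[k] == "-") row1[k] <- "---" else { i <- i + 1; row1[k] <- cod1[i] }
    if (a2[k] == "-") row2[k] <- "---" else { j <- j + 1; row2[k] <- cod2[j] }
  }
  list(focal = paste(row1, collapse = ""),
       ortholog = paste(row2, collapse = ""))
}

# Candidate similar pairs via shared k-mers (cheap prescreen), confirmed by
# local nucleotide alignment score.
.similar_pairs <- function(seqs, min_score, k = 14) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else unique(substring(s, 1:(L - k + 1), k:L))
  })
  owner <- data.frame(kmer = unlist(kmers),
                      gene = rep(seq_len(n), lengths(kmers)))
  shared <- owner[owner$kmer %in% owner$kmer[duplicated(owner$kmer)], ]
  cand <- unique(do.call(rbind, lapply(
    split(shared$gene, shared$kmer),
    function(g) { g <- sort(unique(g)); if (length(g) < 2) NULL
      else t(utils::combn(g, 2)) })))
  if (is.null(cand) || nrow(cand) == 0) return(matrix(integer(0), ncol = 2))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[[cand[r, 1]]], seqs[[cand[r, 2]]], type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
    sc >= min_score
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# Connected components by breadth-first search over an adjacency list.
.components <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Cluster genes into paralogous families
#'
#' Builds an undirected significant-similarity graph (shared 14-mer
#' prescreen followed by local alignment with a score threshold) and
#' returns its connected components. Seeded expansion over such a graph is
#' equivalent to connected components, so the result is invariant to input
#' order. The family representative is the member with the longest CDS,
#' ties broken by the lexicographically smallest transcript id. Downstream
#' statistics treat each family as a single data point.
#'
#' @param genes Data frame with columns \code{gene_id}, \code{cds} and
#'   optionally \code{transcript_id} (defaults to \code{gene_id}).
#' @param min_score Minimum local alignment score (match 1, mismatch -2,
#'   gap open 5, extend 2) for an edge.
#' @return Data frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{family_id} and logical \code{representative}.
#' @export
cluster_families <- function(genes, min_score = 40) {
  stopifnot(nrow(genes) >= 1)
  tid <- if ("transcript_id" %in% names(genes)) genes$transcript_id
         else genes$gene_id
  edges <- .similar_pairs(as.list(genes$cds), min_score)
  comp <- .components(nrow(genes), edges)
  # canonical family ids: order of first appearance
  fam <- paste0("F", match(comp, unique(comp)))
  len <- nchar(genes$cds)
  rep_flag <- logical(nrow(genes))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    best <- idx[order(-len[idx], tid[idx])][1]
    rep_flag[best] <- TRUE
  }
  data.frame(gene_id = genes$gene_id, transcript_id = tid,
             family_id = fam, representative = rep_flag)
}

#' Ortholog divergence filters
#'
#' Applies the pseudogene-contamination filters to pairwise rate
#' estimates. In \code{"human"} mode a pair is dropped when dS >= 0.2 or
#' dN/dS >= 0.5; in \code{"mouse"} mode a pair is kept when dS < 0.3 and
#' dN/dS < 0.5. An undefined ratio (dS = 0) cannot exceed the threshold
#' and therefore passes the ratio condition.
#'
#' @param rates Data frame with columns \code{ds} and \code{ratio} (one
#'   row per pair), e.g. built from \code{\link{pairwise_codon_rates}}.
#' @param mode \code{"human"} or \code{"mouse"}.
#' @return Logical vector: keep the pair.
#' @export
filter_ortholog_pairs <- function(rates, mode = c("human", "mouse")) {
  mode <- match.arg(mode)
  ratio_ok <- is.na(rates$ratio) | rates$ratio < 0.5
  if (mode == "human") !is.na(rates$ds) & rates$ds < 0.2 & ratio_ok
  else !is.na(rates$ds) & rates$ds < 0.3 & ratio_ok
}
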