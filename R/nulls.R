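# The three null models: dinucleotide-pool random hexamer sets, windowed
# codon shuffles, and exhaustive per-motif dinucleotide permutations.

#' Overlapping dinucleotide pool of a motif set
#'
#' Each hexamer contributes its five overlapping dinucleotides (both
#' reading frames), giving a multiset of 5 x n entries from which control
#' hexamers are sampled. Junction dinucleotides spanning two concatenated
#' motifs are deliberately not included, since they would depend on an
#' arbitrary concatenation order.
#'
#' @param motifs Character vector of hexamers.
#' @return Character vector (multiset) of dinucleotides, length
#'   \code{5 * length(motifs)}.
#' @export
dinucleotide_pool <- function(motifs) {
  motifs <- as.character(motifs)
  .check_motifs(motifs)
  unlist(lapply(motifs, function(m) substring(m, 1:5, 2:6)),
         use.names = FALSE)
}

#' Generate dinucleotide-matched control hexamer sets
#'
#' Each control hexamer is the concatenation of three draws (with
#' replacement) from the pool of overlapping dinucleotides of the real
#' set; hexamers belonging to the real set are rejected and redrawn.
#' Duplicate control hexamers within one set are permitted (sampling with
#' replacement); set \code{allow_duplicates = FALSE} to force distinct
#' members.
#'
#' @param real Character vector: the real motif set.
#' @param n_sets Number of control sets.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param allow_duplicates Allow repeated hexamers within a control set.
#' @param max_attempts Rejection-sampling bound per hexamer before the
#'   pool is declared degenerate.
#' @return A list of \code{n_sets} character vectors, each of length
#'   \code{length(real)}, with the seed recorded as an attribute.
#' @export
build_control_sets <- function(real, n_sets = 10000, seed = NULL,
                               allow_duplicates = TRUE,
                               max_attempts = 10000) {
  real <- as.character(real)
  .check_motifs(real)
  pool <- dinucleotide_pool(real)
  .with_seed(seed, {
    draw_set <- function() {
      out <- character(length(real))
      for (i in seq_along(real)) {
        for (att in seq_len(max_attempts)) {
          hex <- paste(sample(pool, 3, replace = TRUE), collapse = "")
          if (hex %in% real) next
          if (!allow_duplicates && hex %in% out[seq_len(i - 1)]) next
          out[i] <- hex
          break
        }
        if (out[i] == "")
          stop("degenerate dinucleotide pool: cannot draw a control ",
               "hexamer outside the real set")
      }
      out
    }
    sets <- replicate(n_sets, draw_set(), simplify = FALSE)
    attr(sets, "seed") <- seed
    sets
  })
}

#' Shuffle codons within fixed-size subregions
#'
#' Divides a CDS into subregions of \code{window} bp (any leftover bases
#' are allocated to the 3'-most subregion; a single merged subregion is
#' used when fewer than two full windows fit) and shuffles the codons
#' within each subregion, preserving the per-subregion codon multiset.
#'
#' @param seq Nucleotide string, length a multiple of 3.
#' @param window Subregion size in bp (multiple of 3).
#' @param seed Optional integer seed.
#' @return Shuffled sequence of the same length.
#' @export
codon_shuffle <- function(seq, window = 294, seed = NULL) {
  L <- nchar(seq)
  if (L %% 3 != 0) stop("sequence length must be a multiple of 3")
  if (window %% 3 != 0) stop("window must be a multiple of 3")
  cods <- .split_codons(seq)
  n_codons <- length(cods)
  w <- window %/% 3L
  n_sub <- max(1L, L %/% window)
  bounds <- if (n_sub == 1L) c(0L, n_codons) else
    c(seq(0L, by = w, length.out = n_sub), n_codons)
  .with_seed(seed, {
    for (i in seq_len(n_sub)) {
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      cods[sel] <- cods[sample(length(sel)) + bounds[i]]
    }
    paste(cods, collapse = "")
  })
}

#' Exhaustive dinucleotide permutation controls for one motif
#'
#' Lists the motif's five overlapping dinucleotides, forms every hexamer
#' obtained by concatenating an ordered selection of three of the five
#' list positions (no position reused), and deduplicates. When the five
#' dinucleotides are all distinct this yields exactly 60 control motifs;
#' the identity tiling (dinucleotides at offsets 0, 2 and 4) reproduces
#' the motif itself and is retained by default.
#'
#' @param motif A single hexamer.
#' @param include_self Keep the original motif when it appears among the
#'   constructions.
#' @return Character vector of control hexamers.
#' @examples
#' length(permutation_controls("GAACTG"))  # 60
#' @export
permutation_controls <- function(motif, include_self = TRUE) {
  if (nchar(motif) != 6 || grepl("[^ACGT]", motif))
    stop("motif must be a hexamer over A/C/G/T")
  d <- substring(motif, 1:5, 2:6)
  out <- character(0)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    if (i == j || i == k || j == k) next
    out <- c(out, paste0(d[i], d[j], d[k]))
  }
  out <- unique(out)
  if (!include_self) out <- setdiff(out, motif)
  out
}
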