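# Standard genetic code tables, per-position degeneracy, and Nei-Gojobori
# (1986) style site/difference counting with Jukes-Cantor correction.
#
# Conventions (documented here once, relied on throughout):
#  * changes that create a stop codon count as nonsynonymous when sites are
#    counted (so GAA has 1/3 synonymous sites, all at position 3);
#  * codon columns containing gaps or stop codons are excluded from counting;
#  * for codon pairs differing at >1 position, path counts are averaged over
#    all orderings whose intermediates are sense codons (all orderings are
#    used if every path passes through a stop).

.ese_env <- new.env(parent = emptyenv())

.codons <- function() {
  if (is.null(.ese_env$codons)) {
    b <- c("T", "C", "A", "G")
    .ese_env$codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  }
  .ese_env$codons
}

.codon_aa <- function() {
  if (is.null(.ese_env$codon_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ese_env$codon_aa <- setNames(as.character(gc[.codons()]), .codons())
  }
  .ese_env$codon_aa
}

.is_stop_codon <- function(codon) .codon_aa()[codon] == "*"

#' Translate a coding sequence
#'
#' Standard-code translation of an ungapped CDS; the terminal stop (if any)
#' is retained as \code{"*"}.
#'
#' @param cds A single nucleotide string with length a multiple of 3.
#' @return A single amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  paste(.codon_aa()[.split_codons(cds)], collapse = "")
}

.split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Per-codon, per-position fold degeneracy: the number of bases (including
# the resident one) that preserve the encoded amino acid at that position.
.degeneracy_table <- function() {
  if (is.null(.ese_env$deg)) {
    aa <- .codon_aa()
    cods <- .codons()
    deg <- matrix(0L, nrow = 64, ncol = 3, dimnames = list(cods, NULL))
    bases <- c("A", "C", "G", "T")
    for (cod in cods) {
      for (pos in 1:3) {
        alt <- vapply(bases, function(b) {
          x <- cod
          substr(x, pos, pos) <- b
          aa[x]
        }, character(1))
        deg[cod, pos] <- sum(alt == aa[cod])
      }
    }
    .ese_env$deg <- deg
  }
  .ese_env$deg
}

#' Annotate per-position codon degeneracy
#'
#' Classifies every CDS position by the fold degeneracy of its codon
#' position under the standard genetic code: the number of bases that leave
#' the amino acid unchanged (1 = nondegenerate, 2, 3, or 4 = fourfold).
#' Fourfold degenerate third positions are the substrate for GC4 and for
#' SNP density denominators.
#'
#' @param cds Ungapped nucleotide string, length a multiple of 3.
#' @return Integer vector of fold classes (1, 2, 3 or 4), one per position.
#' @examples
#' annotate_degeneracy("ATGGCTGAA")  # Met | Ala (GCN) | Glu (GAR)
#' @export
annotate_degeneracy <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  deg <- .degeneracy_table()
  cods <- .split_codons(cds)
  if (!all(cods %in% rownames(deg))) stop("noncanonical bases in CDS")
  as.integer(t(deg[cods, , drop = FALSE]))
}

#' GC content at fourfold degenerate sites
#'
#' @param cds Ungapped CDS string.
#' @return Fraction of G or C bases among fourfold degenerate positions;
#'   \code{NA} if the CDS has none.
#' @export
gc4_content <- function(cds) {
  fold <- annotate_degeneracy(cds)
  sites <- which(fold == 4L)
  if (length(sites) == 0) return(NA_real_)
  b <- strsplit(cds, "", fixed = TRUE)[[1]][sites]
  mean(b %in% c("G", "C"))
}

# NG86 site counts per sense codon: fractional synonymous site count, with
# mutations to stop codons treated as nonsynonymous. Stops get NA.
.ng86_sites <- function() {
  if (is.null(.ese_env$ng86_sites)) {
    aa <- .codon_aa()
    cods <- .codons()
    bases <- c("A", "C", "G", "T")
    s <- setNames(rep(NA_real_, 64), cods)
    for (cod in cods) {
      if (aa[cod] == "*") next
      fs <- 0
      for (pos in 1:3) {
        for (b in bases) {
          if (b == substr(cod, pos, pos)) next
          x <- cod
          substr(x, pos, pos) <- b
          if (aa[x] == aa[cod]) fs <- fs + 1 / 3
        }
      }
      s[cod] <- fs
    }
    .ese_env$ng86_sites <- s
  }
  .ese_env$ng86_sites
}

# Averaged synonymous/nonsynonymous difference counts for one sense codon
# pair, path-enumerated.
.ng86_pair_one <- function(c1, c2) {
  aa <- .codon_aa()
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diffs)
  if (k == 0) return(c(0, 0))
  orders <- switch(as.character(k),
    "1" = list(diffs),
    "2" = list(diffs, rev(diffs)),
    "3" = {
      p <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
      lapply(p, function(i) diffs[i])
    })
  walk <- function(ord) {
    cur <- c1
    sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (aa[nxt] == "*") return(NULL)
      if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk))
  if (length(res) == 0) {
    # every path passes through a stop; use all paths, stop steps nonsyn
    walk_all <- function(ord) {
      cur <- c1
      sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (aa[nxt] != "*" && aa[cur] != "*" && aa[nxt] == aa[cur]) {
          sd <- sd + 1
        } else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(orders, walk_all)
  }
  colMeans(do.call(rbind, res))
}

# 64 x 64 lookup matrices of averaged Sd and Nd (NA when either codon is a
# stop). Built once per session.
.ng86_pair_tables <- function() {
  if (is.null(.ese_env$ng86_sd)) {
    cods <- .codons()
    aa <- .codon_aa()
    sd <- matrix(NA_real_, 64, 64, dimnames = list(cods, cods))
    nd <- sd
    sense <- cods[aa != "*"]
    for (a in sense) for (b in sense) {
      if (a == b) { sd[a, b] <- 0; nd[a, b] <- 0; next }
      v <- .ng86_pair_one(a, b)
      sd[a, b] <- v[1]; nd[a, b] <- v[2]
    }
    .ese_env$ng86_sd <- sd
    .ese_env$ng86_nd <- nd
  }
  list(sd = .ese_env$ng86_sd, nd = .ese_env$ng86_nd)
}

.jc_correct <- function(p) {
  arg <- 1 - 4 / 3 * p
  ifelse(arg > 0, -3 / 4 * log(arg), NA_real_)
}

# Rates from summed NG86 counts. S and N are averaged over the two rows
# before this point.
.rates_from_counts <- function(S, N, Sd, Nd) {
  S <- as.numeric(S); N <- as.numeric(N)
  Sd <- as.numeric(Sd); Nd <- as.numeric(Nd)
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ds <- if (is.na(ps)) NA_real_ else .jc_correct(ps)
  dn <- if (is.na(pn)) NA_real_ else .jc_correct(pn)
  ratio <- if (is.na(ds) || is.na(dn) || ds == 0) NA_real_ else dn / ds
  list(ds = ds, dn = dn, ratio = ratio, ps = ps, pn = pn,
       S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Pairwise synonymous and nonsynonymous rates (NG86 + Jukes-Cantor)
#'
#' Counts fractional synonymous/nonsynonymous sites (averaged over the two
#' rows) and differences per Nei and Gojobori (1986), then applies the
#' Jukes-Cantor correction \eqn{d = -3/4 \log(1 - 4/3 p)}. Codon columns
#' containing gaps (\code{-}) or stop codons in either row are excluded.
#' Mutations to stop codons are treated as nonsynonymous; multi-difference
#' codons are averaged over mutational paths avoiding stop intermediates.
#'
#' @param focal,ortholog Codon-aligned nucleotide strings of equal length
#'   (multiple of 3); gaps allowed as \code{-}.
#' @return A list with \code{ds}, \code{dn}, \code{ratio} (dN/dS, \code{NA}
#'   when dS is 0 or undefined), the uncorrected proportions \code{ps},
#'   \code{pn}, and the underlying counts \code{S}, \code{N}, \code{Sd},
#'   \code{Nd}. \code{ds}/\code{dn} are \code{NA} when the correction
#'   argument is nonpositive (p >= 3/4).
#' @examples
#' pairwise_codon_rates(strrep("GAA", 10),
#'                      paste0(strrep("GAA", 9), "GAG"))$ds
#' @export
pairwise_codon_rates <- function(focal, ortholog) {
  if (nchar(focal) != nchar(ortholog))
    stop("aligned rows must have equal length")
  if (nchar(focal) %% 3 != 0) stop("alignment length must be a multiple of 3")
  c1 <- .split_codons(focal)
  c2 <- .split_codons(ortholog)
  cnt <- .ng86_codon_counts(c1, c2)
  ok <- !is.na(cnt$S)
  if (!any(ok)) stop("no countable codon columns (all gapped or stop)")
  .rates_from_counts(sum(cnt$S[ok]), sum(cnt$N[ok]),
                     sum(cnt$Sd[ok]), sum(cnt$Nd[ok]))
}

# Vectorized per-codon-pair counts; NA for columns with gaps, stops or
# noncanonical characters. S/N are the two-row averages.
.ng86_codon_counts <- function(c1, c2) {
  sites <- .ng86_sites()
  tabs <- .ng86_pair_tables()
  s1 <- sites[c1]
  s2 <- sites[c2]
  idx <- cbind(match(c1, .codons()), match(c2, .codons()))
  bad <- is.na(idx[, 1]) | is.na(idx[, 2])
  idx[bad, ] <- 1L
  Sd <- tabs$sd[idx]
  Nd <- tabs$nd[idx]
  Sd[bad] <- NA_real_
  Nd[bad] <- NA_real_
  S <- (s1 + s2) / 2
  N <- 3 - S
  valid <- !is.na(S) & !is.na(Sd)
  S[!valid] <- NA_real_
  N[!valid] <- NA_real_
  Sd[!valid] <- NA_real_
  Nd[!valid] <- NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}
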