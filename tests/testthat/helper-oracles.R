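# Independent oracle implementations used to cross-check the package's own
# statistics. These deliberately share no code with R/: the NG86 oracle
# enumerates mutational paths recursively over string states, the gamma
# oracle loops over all pairs, and the clustering oracle delegates to
# igraph.

GENCODE <- as.character(Biostrings::GENETIC_CODE)
names(GENCODE) <- names(Biostrings::GENETIC_CODE)

oracle_translate <- function(codon) GENCODE[[codon]]

# NG86 synonymous site count of one sense codon (mutations to stops count
# as nonsynonymous)
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    mut <- codon
    substr(mut, pos, pos) <- b
    if (oracle_translate(mut) == aa) s <- s + 1 / 3
  }
  s
}

# recursive path enumeration of syn/nonsyn differences between two sense
# codons; paths through stop codons are discarded unless all are blocked
oracle_pair_diffs <- function(c1, c2) {
  paths <- function(cur, allow_stops) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(d) == 0) return(list(c(0, 0)))
    out <- list()
    for (pos in d) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      blocked <- oracle_translate(nxt) == "*" && nxt != c2
      if (blocked && !allow_stops) next
      step <- if (oracle_translate(nxt) != "*" &&
                  oracle_translate(cur) != "*" &&
                  oracle_translate(nxt) == oracle_translate(cur))
        c(1, 0) else c(0, 1)
      for (rest in paths(nxt, allow_stops))
        out[[length(out) + 1]] <- step + rest
    }
    out
  }
  res <- paths(c1, allow_stops = FALSE)
  # a path may also hit a stop at the final state c2 (not possible here,
  # both endpoints are sense) or be blocked midway for every ordering
  if (length(res) == 0) res <- paths(c1, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

# full NG86 + JC on two ungapped codon-aligned sense sequences
oracle_ng86 <- function(s1, s2) {
  n <- nchar(s1) %/% 3
  S <- Sd <- Nd <- 0
  for (i in seq_len(n)) {
    a <- substr(s1, 3 * i - 2, 3 * i)
    b <- substr(s2, 3 * i - 2, 3 * i)
    S <- S + (oracle_syn_sites(a) + oracle_syn_sites(b)) / 2
    d <- oracle_pair_diffs(a, b)
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  N <- 3 * n - S
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(ds = jc(Sd / S), dn = jc(Nd / N), S = S, Sd = Sd, Nd = Nd)
}

# naive O(n^2) Goodman-Kruskal gamma
oracle_gamma <- function(x, y) {
  C <- D <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx * dy > 0) C <- C + 1
    if (dx * dy < 0) D <- D + 1
  }
  if (C + D == 0) NA_real_ else (C - D) / (C + D)
}

# random sense codon sequences (no stops) for rate tests
random_sense_cds <- function(n_codons) {
  sense <- names(GENCODE)[GENCODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a sequence at a given per-base rate (any base, may be nonsyn)
mutate_bases <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

# paste n literal (non-overlapping) occurrences of a motif into a region
# of a sequence; used where a test needs exact hit counts and ORF
# preservation is irrelevant
insert_motif <- function(seq, motif, n, from = 1, to = nchar(seq) - 5) {
  if (n == 0) return(seq)
  slots <- seq(from + sample(0:6, 1), to, by = 7)
  for (p in sample(slots, min(n, length(slots))))
    substr(seq, p, p + 5) <- motif
  seq
}

# a small, fast synthetic configuration for module tests
tiny_config <- function(seed, ...) {
  synthetic_config(
    n_genes = 12,
    cds_length_law = function(n) 3L * sample(120:220, n, replace = TRUE),
    seed = seed, ...)
}
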