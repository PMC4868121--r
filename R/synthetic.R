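# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: a negative GC4 gradient across exon numbers, purine-
# rich motifs planted at a controlled excess over dinucleotide expectation
# with a 5' exon-end bias, ortholog pairs whose synonymous divergence is
# scaled down inside motif hits, SNPs with a rare-allele excess inside
# motifs, and retrocopies that inherit their parent's motifs verbatim.
#
# Motif planting rewrites codons synonymously only, so the protein is
# invariant and ORF validity is preserved by construction. The GC4
# gradient is realized by biasing the third-base choice within synonymous
# codon families toward a per-gene target drawn from a linear-in-exon-
# number mean.

.aa_codon_list <- function() {
  if (is.null(.ese_env$aa_codons)) {
    aa <- .codon_aa()
    .ese_env$aa_codons <- split(names(aa), aa)
  }
  .ese_env$aa_codons
}

# synonymous codons sharing the first two bases (third-base family)
.third_base_family <- function(codon) {
  aa <- .codon_aa()
  fam <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  fam[aa[fam] == aa[codon] & aa[fam] != "*"]
}

# per codon and position, the synonymous alternative bases
.syn_alt_table <- function() {
  if (is.null(.ese_env$syn_alts)) {
    aa <- .codon_aa()
    bases <- c("A", "C", "G", "T")
    tab <- list()
    for (cod in .codons()) {
      per_pos <- vector("list", 3)
      for (pos in 1:3) {
        alts <- character(0)
        for (b in bases) {
          if (b == substr(cod, pos, pos)) next
          x <- cod
          substr(x, pos, pos) <- b
          if (aa[x] == aa[cod] && aa[x] != "*") alts <- c(alts, b)
        }
        per_pos[[pos]] <- alts
      }
      tab[[cod]] <- per_pos
    }
    .ese_env$syn_alts <- tab
  }
  .ese_env$syn_alts
}

#' Configuration for synthetic cohorts
#'
#' Defaults describe a cohort of 200 protein-coding genes with a mix of
#' intronless and multi-exon architectures, ESE-like motifs planted at a
#' 25 percent excess over dinucleotide expectation with a twofold 5' exon-
#' end bias, background synonymous divergence of 0.065 substitutions per
#' synonymous site scaled by 0.8 inside motif hits, a 1 percent per-site
#' segregation rate and a twofold rare-allele excess inside motifs.
#'
#' @param n_genes Number of genes (retrocopies included).
#' @param exon_number_law Function n -> integer exon counts (>= 1).
#' @param gc4_intercept,gc4_slope,gc4_sd Per-gene target GC4 is
#'   \code{gc4_intercept + gc4_slope * (exon_count - 1)} plus Gaussian
#'   noise, clipped to [0.1, 0.9]; the negative default slope reproduces
#'   the higher GC content of few-exon genes.
#' @param cds_length_law Function n -> CDS lengths (multiples of 3, >= 300).
#' @param motif_set Hexamer set to plant and scan.
#' @param planted_nd Target fractional excess of motif coverage over
#'   dinucleotide expectation (0 = no planting).
#' @param end_bias Relative planting rate in 69-bp exon-end windows vs
#'   cores (the 5' window gets the full bias, the 3' window half of it).
#' @param ds_background Expected synonymous divergence per synonymous site.
#' @param ese_ds_scaling Multiplier on \code{ds_background} inside motif
#'   hits (<= 1 simulates purifying selection).
#' @param snp_rate Per-site segregation probability.
#' @param rare_excess Multiplier on the rare-allele probability inside
#'   motif hits.
#' @param rare_baseline Baseline probability that a SNP is rare (MAF below
#'   \code{maf_threshold}).
#' @param maf_threshold Rare-allele MAF cutoff.
#' @param retro_fraction Fraction of the cohort generated as retrocopies
#'   of multi-exon parents.
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters.
#' @param seed Integer master seed; identical seeds give byte-identical
#'   cohorts.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    n_genes = 200,
    exon_number_law = function(n) 1L + stats::rnbinom(n, mu = 5, size = 2),
    gc4_intercept = 0.60, gc4_slope = -0.01, gc4_sd = 0.05,
    cds_length_law = function(n) 3L * sample(150:800, n, replace = TRUE),
    motif_set = int3_like_motifs(),
    planted_nd = 0.25,
    end_bias = 2,
    ds_background = 0.065,
    ese_ds_scaling = 0.8,
    snp_rate = 0.01,
    rare_excess = 2,
    rare_baseline = 0.2,
    maf_threshold = 1 / 2000,
    retro_fraction = 0.05,
    intron_meanlog = log(1500), intron_sdlog = 1,
    seed = 1) {
  cfg <- list(n_genes = n_genes, exon_number_law = exon_number_law,
              gc4_intercept = gc4_intercept, gc4_slope = gc4_slope,
              gc4_sd = gc4_sd, cds_length_law = cds_length_law,
              motif_set = as.character(motif_set), planted_nd = planted_nd,
              end_bias = end_bias, ds_background = ds_background,
              ese_ds_scaling = ese_ds_scaling, snp_rate = snp_rate,
              rare_excess = rare_excess, rare_baseline = rare_baseline,
              maf_threshold = maf_threshold,
              retro_fraction = retro_fraction,
              intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
              seed = seed)
  with(cfg, {
    stopifnot(n_genes >= 0, planted_nd >= 0, end_bias > 0,
              ds_background >= 0, ds_background <= 1,
              ese_ds_scaling >= 0, ese_ds_scaling <= 1,
              snp_rate >= 0, snp_rate <= 1, rare_excess >= 0,
              rare_baseline >= 0, rare_baseline <= 1,
              retro_fraction >= 0, retro_fraction <= 1)
  })
  .check_motifs(cfg$motif_set)
  structure(cfg, class = "synthetic_config")
}

# Synonymous-rewrite feasibility and application of one motif at a
# 1-based start position on a codon vector. Returns the modified codon
# vector or NULL when infeasible.
.try_plant <- function(codons, motif, pos) {
  aa <- .codon_aa()
  c1 <- ((pos - 1L) %/% 3L) + 1L
  c2 <- ((pos + 4L) %/% 3L) + 1L
  if (c2 > length(codons)) return(NULL)
  aa_list <- .aa_codon_list()
  new <- codons
  for (cc in c1:c2) {
    lo <- (cc - 1L) * 3L + 1L
    g <- max(pos, lo):min(pos + 5L, lo + 2L)
    off <- g - lo + 1L
    req <- substring(motif, g - pos + 1L, g - pos + 1L)
    cands <- aa_list[[aa[codons[cc]]]]
    ok <- rep(TRUE, length(cands))
    for (t in seq_along(off))
      ok <- ok & substr(cands, off[t], off[t]) == req[t]
    cands <- cands[ok]
    if (length(cands) == 0) return(NULL)
    # prefer the candidate closest to the resident codon
    mism <- vapply(cands, function(x)
      sum(strsplit(x, "")[[1]] != strsplit(codons[cc], "")[[1]]),
      integer(1))
    new[cc] <- cands[order(mism, cands)][1]
  }
  new
}

#' Plant motif occurrences by synonymous rewriting
#'
#' Rewrites codons synonymously so that \code{motif} occurs at \code{n}
#' additional positions; the encoded protein is unchanged. Positions are
#' drawn with the supplied weights; infeasible positions (where no
#' synonymous codon choice can spell the motif) are skipped and redrawn.
#'
#' @param cds CDS string (length a multiple of 3).
#' @param motif Hexamer to plant.
#' @param n Number of occurrences to plant.
#' @param weights Optional per-position weights (length
#'   \code{nchar(cds) - 5}).
#' @param seed Optional integer seed.
#' @return List with \code{cds} (modified sequence) and
#'   \code{planted_starts} (0-based start offsets actually planted).
#' @export
plant_motif_hits <- function(cds, motif, n, weights = NULL, seed = NULL) {
  .with_seed(seed, {
    codons <- .split_codons(cds)
    L <- nchar(cds)
    npos <- L - 5L
    w <- if (is.null(weights)) rep(1, npos) else weights
    stopifnot(length(w) == npos)
    # synonymous realizability is sparse (<1% of random motif/position
    # pairs), so enumerate the feasible positions up front
    feasible <- vapply(seq_len(npos), function(p)
      !is.null(.try_plant(codons, motif, p)), logical(1))
    planted <- integer(0)
    attempts <- 0L
    while (length(planted) < n && any(feasible) &&
           attempts < 20L * max(1L, n) + 100L) {
      attempts <- attempts + 1L
      cand <- which(feasible)
      pos <- if (length(cand) == 1) cand else
        sample(cand, 1, prob = w[cand])
      if (substr(cds, pos, pos + 5L) == motif) {
        feasible[pos] <- FALSE
        next
      }
      res <- .try_plant(codons, motif, pos)  # re-check: codons may differ
      if (is.null(res)) {
        feasible[pos] <- FALSE
        next
      }
      codons <- res
      c1 <- ((pos - 1L) %/% 3L) + 1L
      c2 <- ((pos + 4L) %/% 3L) + 1L
      substr(cds, (c1 - 1L) * 3L + 1L, c2 * 3L) <-
        paste(codons[c1:c2], collapse = "")
      planted <- c(planted, pos - 1L)
      feasible[pos] <- FALSE
    }
    list(cds = cds, planted_starts = sort(planted))
  })
}

# Plant motif hits until scanned coverage of the real set exceeds the
# pre-planting baseline by config$planted_nd (the baseline standing in for
# the dinucleotide expectation, which matches it for unplanted sequence).
# Maintains the codon vector in place and samples positions by inverse-CDF
# lookup for speed.
.plant_to_target <- function(cds, exon_bounds, config) {
  L <- nchar(cds)
  motifs <- config$motif_set
  scan_cov <- function(s) .covered_bases(.merge_hit_runs(
    .starts_for_set(hit_index(s), motifs)))
  C0 <- scan_cov(cds)
  base_cov <- max(C0, 6)
  target <- (1 + config$planted_nd) * base_cov
  if (target > L)
    stop("infeasible config: planted_nd demands motif coverage > 1 ",
         sprintf("(baseline %.3f, requested excess %.2f)",
                 base_cov / L, config$planted_nd))
  w <- .position_weights(L, exon_bounds, config$end_bias)
  cw <- cumsum(w)
  codons <- .split_codons(cds)
  planted <- integer(0)
  cov <- C0
  attempts <- 0L
  max_att <- 50L + 10L * ceiling((target - C0) / 6)
  nm <- length(motifs)
  while (cov < target && attempts < max_att) {
    attempts <- attempts + 1L
    pos <- findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L
    # few motifs are synonymously realizable at any given position, so try
    # the set in random order and keep the first that fits
    res <- NULL
    for (mi in sample.int(nm)) {
      m <- motifs[mi]
      if (substr(cds, pos, pos + 5L) == m) next
      res <- .try_plant(codons, m, pos)
      if (!is.null(res)) break
    }
    if (is.null(res)) next
    codons <- res
    c1 <- ((pos - 1L) %/% 3L) + 1L
    c2 <- ((pos + 4L) %/% 3L) + 1L
    substr(cds, (c1 - 1L) * 3L + 1L, c2 * 3L) <-
      paste(codons[c1:c2], collapse = "")
    planted <- c(planted, pos - 1L)
    cov <- scan_cov(cds)
  }
  list(cds = cds, planted = sort(planted))
}

# interior random codons with GC-biased third bases
.random_codons <- function(n, gc_target) {
  aa <- .codon_aa()
  sense <- .codons()[aa != "*"]
  cods <- sample(sense, n, replace = TRUE)
  vapply(cods, function(cod) {
    fam <- .third_base_family(cod)
    if (length(fam) < 2) return(cod)
    b3 <- substr(fam, 3, 3)
    w <- ifelse(b3 %in% c("G", "C"), gc_target, 1 - gc_target)
    sample(fam, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

# planting weights per hexamer start: 5' exon-end windows get end_bias,
# 3' windows half the bias, cores 1
.position_weights <- function(L, exon_bounds, end_bias) {
  w <- rep(1, L - 5L)
  for (r in seq_len(nrow(exon_bounds))) {
    s <- exon_bounds[r, 1]; e <- exon_bounds[r, 2]  # 0-based half-open
    five <- (s + 1):min(s + 69, e)
    three <- max(s + 1, e - 69 + 1):e
    w[five[five <= L - 5]] <- end_bias
    w[three[three <= L - 5]] <-
      pmax(w[three[three <= L - 5]], 1 + (end_bias - 1) / 2)
  }
  w
}

.gene_ids <- function(n, prefix = "G")
  sprintf("%s%04d", prefix, seq_len(n))

#' Evolve a synonymous-only ortholog of a CDS
#'
#' Produces a gap-free codon alignment of the gene against a mutated copy
#' in which only synonymous substitutions occur: at each codon position
#' with synonymous alternatives, a substitution happens with probability
#' \code{ds_background} per synonymous site (scaled by
#' \code{ese_ds_scaling} inside motif hits), so the translation of the two
#' rows is identical by construction.
#'
#' @param cds CDS string.
#' @param config A \code{\link{synthetic_config}} (fields
#'   \code{ds_background}, \code{ese_ds_scaling}, \code{motif_set} used).
#' @param seed Optional integer seed.
#' @return List with \code{focal} and \code{ortholog} (equal-length,
#'   ungapped).
#' @export
evolve_ortholog <- function(cds, config, seed = NULL) {
  if (config$ds_background == 0)
    return(list(focal = cds, ortholog = cds))
  mask <- find_hits(cds, config$motif_set)$coverage
  alts <- .syn_alt_table()
  .with_seed(seed, {
    codons <- .split_codons(cds)
    for (j in seq_along(codons)) {
      per_pos <- alts[[codons[j]]]
      for (pos in 1:3) {
        a <- per_pos[[pos]]
        if (length(a) == 0) next
        site <- (j - 1L) * 3L + pos
        p <- config$ds_background * (length(a) / 3) *
          (if (mask[site]) config$ese_ds_scaling else 1)
        if (stats::runif(1) < p) {
          b <- if (length(a) == 1) a else sample(a, 1)
          substr(codons[j], pos, pos) <- b
          per_pos <- alts[[codons[j]]]
        }
      }
    }
    list(focal = cds, ortholog = paste(codons, collapse = ""))
  })
}

#' Simulate SNPs on a CDS
#'
#' Each site segregates with probability \code{snp_rate}. Alternative
#' alleles are degeneracy consistent: a synonymous alternative is chosen
#' where one exists (consequence \code{"synonymous"}), otherwise a random
#' other base (\code{"nonsynonymous"}). SNPs are rare (MAF below
#' \code{maf_threshold}) with probability \code{rare_baseline}, multiplied
#' by \code{rare_excess} inside motif hits; MAFs are uniform within the
#' rare and common strata.
#'
#' @param cds CDS string.
#' @param config A \code{\link{synthetic_config}}.
#' @param seed Optional integer seed.
#' @return Data frame with \code{cds_pos} (0-based), \code{ref},
#'   \code{alt}, \code{maf}, \code{consequence}.
#' @export
simulate_snps <- function(cds, config, seed = NULL) {
  if (config$snp_rate == 0)
    return(data.frame(cds_pos = integer(0), ref = character(0),
                      alt = character(0), maf = numeric(0),
                      consequence = character(0)))
  mask <- find_hits(cds, config$motif_set)$coverage
  alts <- .syn_alt_table()
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    L <- nchar(cds)
    seg <- which(stats::runif(L) < config$snp_rate)
    if (length(seg) == 0)
      return(data.frame(cds_pos = integer(0), ref = character(0),
                        alt = character(0), maf = numeric(0),
                        consequence = character(0)))
    codons <- .split_codons(cds)
    rows <- lapply(seg, function(s) {
      j <- ((s - 1L) %/% 3L) + 1L
      pos <- s - (j - 1L) * 3L
      ref <- substr(codons[j], pos, pos)
      syn <- alts[[codons[j]]][[pos]]
      if (length(syn) > 0) {
        alt <- if (length(syn) == 1) syn else sample(syn, 1)
        cons <- "synonymous"
      } else {
        others <- setdiff(bases, ref)
        alt <- sample(others, 1)
        cons <- "nonsynonymous"
      }
      p_rare <- min(0.95, config$rare_baseline *
                      (if (mask[s]) config$rare_excess else 1))
      maf <- if (stats::runif(1) < p_rare)
        stats::runif(1, 1e-9, config$maf_threshold * 0.999)
      else stats::runif(1, config$maf_threshold, 0.5)
      data.frame(cds_pos = s - 1L, ref = ref, alt = alt, maf = maf,
                 consequence = cons)
    })
    do.call(rbind, rows)
  })
}

#' Derive a retrocopy from a multi-exon parent
#'
#' Returns an intronless gene whose CDS equals the parent CDS up to an
#' optional number of synonymous substitutions (keeping dN at 0 and
#' inheriting the parent's motif content essentially verbatim), plus the
#' genomic interval to emit as a retrocopy annotation.
#'
#' @param parent List with \code{gene_id}, \code{cds}, \code{exon_count}.
#' @param n_substitutions Number of synonymous substitutions to apply.
#' @param genomic_start 0-based genomic start for the product's locus.
#' @param chrom Chromosome name for the product.
#' @param seed Optional integer seed.
#' @return List with \code{gene} (fields \code{gene_id}, \code{cds},
#'   \code{exon_count} = 1, \code{parent_id}, genomic coordinates) and
#'   \code{interval} (data frame \code{chrom}, \code{start}, \code{end}).
#' @export
derive_retrocopy <- function(parent, n_substitutions = 0,
                             genomic_start = 0, chrom = "chrS",
                             seed = NULL) {
  if (parent$exon_count < 2)
    stop("parent must have at least 2 exons")
  alts <- .syn_alt_table()
  cds <- .with_seed(seed, {
    codons <- .split_codons(parent$cds)
    done <- 0L
    guard <- 0L
    while (done < n_substitutions && guard < 100L * (n_substitutions + 1L)) {
      guard <- guard + 1L
      j <- sample.int(length(codons), 1)
      pos <- sample.int(3, 1)
      a <- alts[[codons[j]]][[pos]]
      if (length(a) == 0) next
      substr(codons[j], pos, pos) <- if (length(a) == 1) a else sample(a, 1)
      done <- done + 1L
    }
    paste(codons, collapse = "")
  })
  L <- nchar(cds)
  list(gene = list(gene_id = paste0("R_", parent$gene_id), cds = cds,
                   exon_count = 1L, parent_id = parent$gene_id,
                   chrom = chrom, g_start = genomic_start,
                   g_end = genomic_start + L),
       interval = data.frame(chrom = chrom, start = genomic_start,
                             end = genomic_start + L))
}

#' Generate a synthetic cohort
#'
#' Produces genes, gap-free ortholog codon alignments, SNP tables,
#' retrocopy annotations and a truth table of planted quantities, all
#' deterministically derived from the configuration seed via named
#' substreams (so identical seeds give byte-identical cohorts).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return Object of class \code{ese_cohort}: list with \code{genes},
#'   \code{exons}, \code{ortholog_pairs}, \code{snps}, \code{retro},
#'   \code{truth} and \code{config}.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  empty <- function() data.frame()
  if (n == 0)
    return(structure(list(
      genes = data.frame(gene_id = character(0)), exons = empty(),
      ortholog_pairs = list(), snps = empty(),
      retro = data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), name = character(0)),
      truth = data.frame(gene_id = character(0)), config = config),
      class = "ese_cohort"))

  seed <- config$seed
  exon_counts <- .with_seed(substream_seed(seed, "exon_counts"),
                            pmax(1L, as.integer(config$exon_number_law(n))))
  n_retro <- min(round(config$retro_fraction * n), n - 1)
  if (sum(exon_counts >= 2) == 0) n_retro <- 0
  n_base <- n - n_retro
  exon_counts <- exon_counts[seq_len(n_base)]
  lens <- .with_seed(substream_seed(seed, "lengths"),
                     as.integer(config$cds_length_law(n_base)))
  stopifnot(all(lens %% 3 == 0), all(lens >= 300))
  ids <- .gene_ids(n_base)

  genes <- vector("list", n_base)
  exon_tabs <- vector("list", n_base)
  truth <- vector("list", n_base)
  g_off <- 0L
  for (i in seq_len(n_base)) {
    gseed <- substream_seed(seed, paste0("gene", i))
    gene <- .with_seed(gseed, {
      L <- lens[i]
      ex <- exon_counts[i]
      gc_t <- min(0.9, max(0.1, config$gc4_intercept +
                             config$gc4_slope * (ex - 1) +
                             stats::rnorm(1, 0, config$gc4_sd)))
      interior <- .random_codons(L %/% 3L - 2L, gc_t)
      stop_cod <- sample(.STOPS, 1)
      cds <- paste(c("ATG", interior, stop_cod), collapse = "")
      # exon boundaries on the CDS (0-based half-open)
      cuts <- if (ex > 1) {
        avail <- setdiff(seq(20L, L - 20L), integer(0))
        sort(sample(avail, ex - 1L))
      } else integer(0)
      bounds <- cbind(c(0L, cuts), c(cuts, L))
      # planting: add hits until scanned coverage exceeds the pre-planting
      # baseline (a stand-in for the dinucleotide expectation) by planted_nd
      planted <- integer(0)
      if (config$planted_nd > 0 && length(config$motif_set) > 0) {
        res <- .plant_to_target(cds, bounds, config)
        cds <- res$cds
        planted <- res$planted
      }
      introns <- if (ex > 1)
        pmax(60L, as.integer(round(stats::rlnorm(ex - 1L,
                                                 config$intron_meanlog,
                                                 config$intron_sdlog))))
      else integer(0)
      list(cds = cds, exon_count = ex, bounds = bounds, introns = introns,
           planted = planted)
    })
    L <- nchar(gene$cds)
    el <- gene$bounds[, 2] - gene$bounds[, 1]
    ex_g_start <- g_off + cumsum(c(0L, if (gene$exon_count > 1)
      el[-gene$exon_count] + gene$introns else integer(0)))
    exon_tabs[[i]] <- data.frame(
      gene_id = ids[i],
      exon_index = seq_len(gene$exon_count),
      cds_start = gene$bounds[, 1], cds_end = gene$bounds[, 2],
      g_start = ex_g_start,
      g_end = ex_g_start + (gene$bounds[, 2] - gene$bounds[, 1]),
      frame_offset = gene$bounds[, 1] %% 3L)
    span <- L + sum(gene$introns)
    genes[[i]] <- data.frame(
      gene_id = ids[i], transcript_id = sub("^G", "T", ids[i]),
      cds = gene$cds, exon_count = gene$exon_count, cds_length = L,
      mean_intron_size = if (length(gene$introns)) mean(gene$introns) else 0,
      intron_density = (gene$exon_count - 1) / L,
      gc4 = gc4_content(gene$cds),
      chrom = "chrS", g_start = g_off, g_end = g_off + span)
    truth[[i]] <- data.frame(
      gene_id = ids[i], planted_sites = length(gene$planted),
      ds_scaling = config$ese_ds_scaling,
      rare_excess = config$rare_excess,
      is_retrocopy = FALSE, parent_id = NA_character_)
    g_off <- g_off + span + 1000L
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exon_tabs)
  truth <- do.call(rbind, truth)

  # retrocopies derived from multi-exon parents
  retro <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0))
  if (n_retro > 0) {
    parents <- .with_seed(substream_seed(seed, "retro_parents"), {
      cand <- which(genes$exon_count >= 2)
      sample(cand, n_retro, replace = length(cand) < n_retro)
    })
    for (r in seq_len(n_retro)) {
      pi <- parents[r]
      rc <- derive_retrocopy(
        list(gene_id = genes$gene_id[pi], cds = genes$cds[pi],
             exon_count = genes$exon_count[pi]),
        n_substitutions = 0, genomic_start = g_off, chrom = "chrS",
        seed = substream_seed(seed, paste0("retro", r)))
      L <- nchar(rc$gene$cds)
      rid <- rc$gene$gene_id
      genes <- rbind(genes, data.frame(
        gene_id = rid, transcript_id = paste0("T", rid), cds = rc$gene$cds,
        exon_count = 1L, cds_length = L, mean_intron_size = 0,
        intron_density = 0, gc4 = gc4_content(rc$gene$cds),
        chrom = "chrS", g_start = g_off, g_end = g_off + L))
      exons <- rbind(exons, data.frame(
        gene_id = rid, exon_index = 1L, cds_start = 0L, cds_end = L,
        g_start = g_off, g_end = g_off + L, frame_offset = 0L))
      truth <- rbind(truth, data.frame(
        gene_id = rid, planted_sites = truth$planted_sites[pi],
        ds_scaling = config$ese_ds_scaling,
        rare_excess = config$rare_excess,
        is_retrocopy = TRUE, parent_id = genes$gene_id[pi]))
      retro <- rbind(retro, cbind(rc$interval, name = rid))
      g_off <- g_off + L + 1000L
    }
  }

  orthologs <- lapply(seq_len(nrow(genes)), function(i)
    evolve_ortholog(genes$cds[i], config,
                    seed = substream_seed(seed, paste0("orth", i))))
  names(orthologs) <- genes$gene_id
  snps <- lapply(seq_len(nrow(genes)), function(i) {
    s <- simulate_snps(genes$cds[i], config,
                       seed = substream_seed(seed, paste0("snp", i)))
    if (nrow(s) > 0) cbind(gene_id = genes$gene_id[i], s) else NULL
  })
  snps <- do.call(rbind, Filter(Negate(is.null), snps))
  if (is.null(snps))
    snps <- data.frame(gene_id = character(0), cds_pos = integer(0),
                       ref = character(0), alt = character(0),
                       maf = numeric(0), consequence = character(0))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, ortholog_pairs = orthologs,
                 snps = snps, retro = retro, truth = truth,
                 config = config),
            class = "ese_cohort")
}

#' @export
print.ese_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$genes), "genes (",
      sum(x$genes$exon_count == 1), "intronless,",
      sum(x$truth$is_retrocopy), "retrocopies ),",
      nrow(x$snps), "SNPs, seed", x$config$seed, "\n")
  invisible(x)
}
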