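# Orchestration: runs the analysis stages over a cohort (synthetic or read
# from files) and produces a machine-readable report.

#' Pipeline configuration
#'
#' Either supply a \code{cohort} (an \code{ese_cohort}, e.g. from
#' \code{\link{make_cohort}}) or file inputs (\code{cds_fasta},
#' \code{motif_file}, optional \code{snp_tsv}, \code{retro_bed}).
#'
#' @param cohort Optional \code{ese_cohort}.
#' @param cds_fasta,motif_file,snp_tsv,retro_bed Optional input paths.
#' @param n_control_sets Control sets for density enrichment.
#' @param n_control_sets_ds Control sets for the dS stage (smaller by
#'   default, as each set requires a full rate computation).
#' @param n_quantile_bins Quantile bins for intron-containing genes
#'   (capped at half the number of positive data points).
#' @param leave_k_iterations Iterations for the retrocopy leave-k-out
#'   stage (0 skips it).
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for the JSON report and TSVs.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(cohort = NULL, cds_fasta = NULL, motif_file = NULL,
                       snp_tsv = NULL, retro_bed = NULL,
                       n_control_sets = 1000, n_control_sets_ds = 200,
                       n_quantile_bins = 48, leave_k_iterations = 0,
                       seed = 1, out_dir = NULL) {
  if (is.null(cohort) && is.null(cds_fasta))
    stop("either a cohort or a CDS FASTA is required")
  structure(list(cohort = cohort, cds_fasta = cds_fasta,
                 motif_file = motif_file, snp_tsv = snp_tsv,
                 retro_bed = retro_bed, n_control_sets = n_control_sets,
                 n_control_sets_ds = n_control_sets_ds,
                 n_quantile_bins = n_quantile_bins,
                 leave_k_iterations = leave_k_iterations,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

# genes x sets matrix of covered bases, reusing per-gene hit indices
.coverage_matrix <- function(idxs, sets) {
  vapply(sets, function(s)
    vapply(idxs, function(ix)
      as.numeric(.covered_bases(.merge_hit_runs(.starts_for_set(ix, s)))),
      numeric(1)),
    numeric(length(idxs)))
}

# median per-data-point (family-averaged) density for one coverage column
.median_point_density <- function(cov, lens, fam_rows) {
  d <- cov / lens
  stats::median(vapply(fam_rows, function(r) mean(d[r]), numeric(1)))
}

#' Run the full analysis pipeline
#'
#' Stages: CDS validation and paralog clustering; motif scanning;
#' dinucleotide-matched control sets; density enrichment (median
#' family-averaged density with ND and empirical p) for intronless and
#' intron-containing genes separately; concatenated dS in motif regions;
#' SNP density and low-MAF fraction; mean-intron-size binned per-motif
#' matrix with trend classification; retrocopy calls and (optionally)
#' leave-k-out resampling. Identical configuration and seed give an
#' identical report.
#'
#' @param config A \code{\link{run_config}}.
#' @return Report list (class \code{ese_report}); written as JSON/TSV when
#'   \code{out_dir} is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  # ---- prep ------------------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    motifs <- cohort$config$motif_set
  } else {
    seqs <- read_cds_fasta(config$cds_fasta)
    if (length(seqs) == 0) stop("prep stage: empty CDS FASTA")
    motifs <- if (is.null(config$motif_file)) int3_like_motifs()
              else read_motifs(config$motif_file)
    genes <- data.frame(gene_id = names(seqs), transcript_id = names(seqs),
                        cds = unname(seqs),
                        exon_count = 1L, cds_length = nchar(seqs),
                        mean_intron_size = 0, intron_density = 0,
                        gc4 = vapply(seqs, gc4_content, numeric(1)))
    cohort <- list(genes = genes, exons = data.frame(),
                   ortholog_pairs = list(),
                   snps = if (is.null(config$snp_tsv)) data.frame()
                          else read_snp_table(config$snp_tsv),
                   retro = if (is.null(config$retro_bed))
                     data.frame(chrom = character(0), start = integer(0),
                                end = integer(0))
                   else read_bed(config$retro_bed),
                   truth = data.frame())
  }
  genes <- cohort$genes
  if (nrow(genes) == 0) stop("prep stage: no genes")
  verdicts <- lapply(genes$cds, validate_cds)
  keep <- vapply(verdicts, `[[`, logical(1), "pass")
  note("prep: %d/%d CDSs pass validation", sum(keep), length(keep))
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) stop("prep stage: no genes survive validation")
  fams <- cluster_families(genes)
  note("prep: %d paralogous families (%d nonsingleton)",
       length(unique(fams$family_id)),
       sum(table(fams$family_id) > 1))

  # ---- scan + controls -------------------------------------------------
  idxs <- lapply(genes$cds, hit_index)
  lens <- genes$cds_length
  controls <- build_control_sets(motifs, config$n_control_sets,
                                 seed = substream_seed(seed, "controls"))
  cov_real <- .coverage_matrix(idxs, list(motifs))[, 1]
  cov_ctrl <- .coverage_matrix(idxs, controls)

  # ---- enrichment per architecture group -------------------------------
  groups <- list(intronless = which(genes$exon_count == 1),
                 intron_containing = which(genes$exon_count > 1))
  enrichment <- lapply(groups, function(rows) {
    if (length(rows) == 0) return(NULL)
    fr <- split(seq_along(rows), fams$family_id[rows])
    obs <- .median_point_density(cov_real[rows], lens[rows], fr)
    null <- apply(cov_ctrl[rows, , drop = FALSE], 2,
                  .median_point_density, lens = lens[rows], fam_rows = fr)
    nd <- normalized_density(obs, null)
    list(n_genes = length(rows), n_points = length(fr),
         median_density = obs, null_mean = nd$null_mean, nd = nd$nd,
         p_enrich = nd$p_enrich, p_depletion = nd$p_depletion)
  })
  note("enrichment: intronless median density %s",
       if (is.null(enrichment$intronless)) "NA" else
         signif(enrichment$intronless$median_density, 4))

  # ---- selection -------------------------------------------------------
  selection <- NULL
  if (length(cohort$ortholog_pairs) > 0) {
    reps <- fams$gene_id[fams$representative]
    reps <- intersect(reps, names(cohort$ortholog_pairs))
    ds_controls <- controls[seq_len(min(config$n_control_sets_ds,
                                        length(controls)))]
    ds <- concatenated_ds(cohort$ortholog_pairs[reps], motifs, ds_controls)
    selection <- list(ds = list(observed = ds$observed_ds,
                                null_mean = mean(ds$null_ds, na.rm = TRUE),
                                normalized = ds$normalized_ds, p = ds$p))
    note("selection: concatenated dS %.4g (normalized %.3g, p = %.3g)",
         ds$observed_ds, ds$normalized_ds, ds$p)
  }
  if (nrow(cohort$snps) > 0) {
    snp_controls <- controls[seq_len(min(config$n_control_sets_ds,
                                         length(controls)))]
    snp <- snp_statistics(genes, cohort$snps, motifs,
                          control_sets = snp_controls,
                          families = fams[c("gene_id", "family_id")],
                          seed = substream_seed(seed, "snp_reps"))
    selection$snp <- snp[setdiff(names(snp), "replicates")]
  }

  # ---- architecture ----------------------------------------------------
  architecture <- NULL
  fam_ids <- sort(unique(fams$family_id))
  fam_mis <- vapply(split(genes$mean_intron_size, fams$family_id)[fam_ids],
                    mean, numeric(1))
  n_pos <- sum(fam_mis > 0)
  if (n_pos >= 4) {
    nq <- min(config$n_quantile_bins, max(2, n_pos %/% 2))
    if (nq < config$n_quantile_bins)
      note("architecture: reducing quantile bins to %d for %d points",
           nq, n_pos)
    bins <- assign_bins(fam_mis, nq)
    mat <- motif_bin_matrix(genes, motifs, bins,
                            families = fams[c("gene_id", "family_id")])
    trends <- motif_trend_tests(mat)
    architecture <- list(n_bins = bins$n_bins,
                         trend_classes = table(trends$class),
                         trends = trends)
  }

  # ---- retrocopies -----------------------------------------------------
  retro <- NULL
  if (nrow(cohort$retro) > 0 && all(c("chrom", "g_start") %in% names(genes))) {
    calls <- broad_retrocopy_calls(
      data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = genes$g_start, end = genes$g_end),
      cohort$retro)
    broad <- calls$gene_id[calls$tier == "broad"]
    retro <- list(n_broad = length(broad), broad_ids = broad)
    note("retro: %d broad-set calls", length(broad))
    il <- genes$gene_id[genes$exon_count == 1]
    broad_il <- intersect(broad, il)
    if (config$leave_k_iterations > 0 && length(broad_il) > 0 &&
        length(broad_il) < length(il)) {
      row_of <- match(il, genes$gene_id)
      statistic <- function(ids) {
        rows <- row_of[il %in% ids]
        fr <- split(seq_along(rows), fams$family_id[rows])
        obs <- .median_point_density(cov_real[rows], lens[rows], fr)
        null <- apply(cov_ctrl[rows, , drop = FALSE], 2,
                      .median_point_density, lens = lens[rows],
                      fam_rows = fr)
        nd <- normalized_density(obs, null)
        c(nd = nd$nd, p = nd$p_enrich)
      }
      lko <- leave_k_out(il, statistic, broad_il,
                         iterations = config$leave_k_iterations,
                         seed = substream_seed(seed, "leave_k_out"))
      retro$leave_k_out <- lko[c("full", "true_delta", "p_nd", "p_p")]
    }
  }

  report <- structure(
    list(seed = seed, n_genes = nrow(genes),
         n_control_sets = config$n_control_sets,
         enrichment = enrichment, selection = selection,
         architecture = architecture, retro = retro, log = log),
    class = "ese_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    ser <- rapply(unclass(report), function(x)
      if (is.table(x)) as.list(x) else x, how = "replace")
    jsonlite::write_json(ser, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    .write_tsv(fams, file.path(config$out_dir, "families.tsv"))
    if (!is.null(architecture))
      .write_tsv(architecture$trends,
                 file.path(config$out_dir, "motif_trends.tsv"))
  }
  report
}

#' @export
print.ese_report <- function(x, ...) {
  cat("esevol pipeline report (seed", x$seed, ",", x$n_genes, "genes)\n")
  for (g in names(x$enrichment)) {
    e <- x$enrichment[[g]]
    if (is.null(e)) next
    cat(sprintf("  %s: median density %.4g, ND %.3g, enrichment p %.3g\n",
                g, e$median_density, e$nd, e$p_enrich))
  }
  if (!is.null(x$selection$ds))
    cat(sprintf("  dS in motif regions: %.4g (normalized %.3g, p %.3g)\n",
                x$selection$ds$observed, x$selection$ds$normalized,
                x$selection$ds$p))
  if (!is.null(x$retro))
    cat("  broad retrocopy calls:", x$retro$n_broad, "\n")
  invisible(x)
}
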