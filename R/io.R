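# Standard-format I/O: FASTA via Biostrings, BED (0-based half-open) and
# TSV via base utilities, JSON config echoes via jsonlite.

#' Read CDS sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = record ids).
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write CDS sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a SNP table
#'
#' Tab-separated with header columns \code{gene_id},
#' \code{cds_pos_0based}, \code{ref}, \code{alt}, \code{maf} and
#' optionally \code{consequence}.
#'
#' @param path File path.
#' @return Data frame with a \code{cds_pos} column (0-based).
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("cds_pos_0based" %in% names(df))
    names(df)[names(df) == "cds_pos_0based"] <- "cds_pos"
  df
}

#' Read a BED file (first 3-6 columns)
#'
#' @param path File path.
#' @return Data frame with \code{chrom}, \code{start}, \code{end} and,
#'   when present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.write_bed <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

#' Write a synthetic cohort to disk
#'
#' Emits CDS FASTA, exon and retrocopy BED (0-based half-open), SNP and
#' truth TSV, and a JSON echo of the configuration including the seed.
#'
#' @param cohort An \code{ese_cohort}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(setNames(cohort$genes$cds, cohort$genes$gene_id),
                  file.path(dir, "cds.fasta"))
  ex <- cohort$exons
  if (nrow(ex) > 0)
    .write_bed(data.frame(ex$gene_id, ex$cds_start, ex$cds_end,
                          paste0("exon", ex$exon_index)),
               file.path(dir, "exons_cds.bed"))
  if (nrow(cohort$retro) > 0)
    .write_bed(cohort$retro, file.path(dir, "retrocopies.bed"))
  snp <- cohort$snps
  names(snp)[names(snp) == "cds_pos"] <- "cds_pos_0based"
  .write_tsv(snp, file.path(dir, "snps.tsv"))
  .write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cfg <- cohort$config
  cfg$exon_number_law <- NULL
  cfg$cds_length_law <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write motif hits as BED6
#'
#' One record per motif hit, with the gene id as the contig, 0-based
#' half-open hit coordinates, and the motif in the name column.
#'
#' @param profiles Named list of \code{hit_profile} objects (names = gene
#'   ids).
#' @param path Output path.
#' @export
write_hits_bed <- function(profiles, path) {
  rows <- list()
  for (g in names(profiles)) {
    hs <- profiles[[g]]$hit_starts
    for (m in names(hs))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = g, start = hs[[m]], end = hs[[m]] + 6L, name = m,
        score = 0L, strand = "+")
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  df <- df[order(df$chrom, df$start, df$name), ]
  .write_bed(df, path)
  invisible(path)
}

#' Serialize control motif sets
#'
#' Writes one plain motif-list file per control set
#' (\code{set_00001.txt}, ...) plus a sidecar JSON recording the seed and
#' set count.
#'
#' @param sets List of control sets (from
#'   \code{\link{build_control_sets}}).
#' @param dir Output directory.
#' @export
write_control_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sets))
    writeLines(sets[[i]], file.path(dir, sprintf("set_%05d.txt", i)))
  jsonlite::write_json(
    list(n_sets = length(sets), set_size = length(sets[[1]]),
         seed = attr(sets, "seed")),
    file.path(dir, "control_sets.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
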