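# Motif set handling: reading/writing plain hexamer lists, validation, and
# the composition-based median splits used for subset analyses.

.check_motifs <- function(motifs) {
  if (length(motifs) == 0) stop("motif set is empty")
  if (any(nchar(motifs) != 6)) stop("all motifs must be hexamers")
  if (any(grepl("[^ACGT]", motifs))) stop("motifs must be over A/C/G/T")
  if (anyDuplicated(motifs)) stop("duplicate motifs in set")
  invisible(motifs)
}

#' Read a motif set from a plain text file
#'
#' One hexamer per line; blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of validated hexamers, with the file's base
#'   name attached as the \code{"name"} attribute.
#' @export
read_motifs <- function(path) {
  x <- readLines(path)
  x <- toupper(trimws(sub("#.*", "", x)))
  x <- x[nzchar(x)]
  .check_motifs(x)
  attr(x, "name") <- sub("\\.[^.]*$", "", basename(path))
  x
}

#' Write a motif set
#'
#' @param motifs Character vector of hexamers.
#' @param path Output file path.
#' @export
write_motifs <- function(motifs, path) {
  .check_motifs(as.character(motifs))
  writeLines(as.character(motifs), path)
  invisible(path)
}

#' Packaged synthetic ESE-like motif set
#'
#' Returns the 84 purine/adenine-rich hexamers packaged with esevol as a
#' synthetic stand-in for a high-confidence exonic splice enhancer set
#' (such sets are typically intersections of published ESE collections).
#' The motifs are synthetic: they emulate the composition of real ESE
#' hexamers but are not the experimentally derived set.
#'
#' @return Character vector of 84 hexamers.
#' @export
int3_like_motifs <- function() {
  read_motifs(system.file("extdata", "synthetic_int3_like_motifs.txt",
                          package = "esevol", mustWork = TRUE))
}

#' Split a motif set by purine or GC content
#'
#' Orders motifs by per-motif purine (A+G) or GC (G+C) base counts and
#' splits along the median; motifs falling on the median are assigned to
#' the high set.
#'
#' @param motifs Character vector of hexamers.
#' @param property \code{"purine"} or \code{"gc"}.
#' @return A list with elements \code{high} and \code{low} (disjoint, with
#'   union equal to the input).
#' @examples
#' split_motifs(c("GCAAAA", "GCGCAA", "GCGCAA", "GGGGCC")[-3], "gc")
#' @export
split_motifs <- function(motifs, property = c("purine", "gc")) {
  property <- match.arg(property)
  motifs <- as.character(motifs)
  .check_motifs(motifs)
  chars <- if (property == "purine") c("A", "G") else c("G", "C")
  cnt <- vapply(strsplit(motifs, "", fixed = TRUE),
                function(b) sum(b %in% chars), integer(1))
  med <- stats::median(cnt)
  list(high = motifs[cnt >= med], low = motifs[cnt < med])
}
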