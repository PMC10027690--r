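#' Read an organelle genome from FASTA
#'
#' Loads contig sequences into an `editome_genome` object: a named list with
#' `$seq` (named character vector of uppercase A/C/G/T/N sequences) and
#' `$circular` (named logical, one flag per contig). Circularity defaults to
#' `FALSE` for every contig and can be toggled with `circular`; coordinate
#' maps for features spanning the origin of a circular contig wrap around via
#' virtual concatenation.
#'
#' @param path Path to a FASTA file.
#' @param circular Either a single logical recycled to all contigs, or a named
#'   logical vector keyed by contig id.
#' @return An object of class `editome_genome`.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  # read as raw strings first: DNA parsing would silently drop characters
  # outside the DNA alphabet, which we want to reject instead
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stopf("FASTA file contains no records: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stopf("duplicate contig ids in FASTA: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("illegal characters (non-ACGTN) in contig(s): %s",
                      paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stopf("empty sequence in FASTA: %s", path)
  genome(seqs, circular)
}

#' Construct a genome object from in-memory sequences
#'
#' @param seq Named character vector of contig sequences (A/C/G/T/N).
#' @param circular Logical flag(s) as in [read_genome_fasta()].
#' @return An `editome_genome` object.
#' @export
genome <- function(seq, circular = FALSE) {
  if (is.null(names(seq)) || any(names(seq) == ""))
    stopf("all contigs must be named")
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) stopf("contig sequences restricted to A/C/G/T/N")
  if (any(nchar(seq) == 0)) stopf("contig sequences must be non-empty")
  if (length(circular) == 1 && is.null(names(circular)))
    circular <- stats::setNames(rep(circular, length(seq)), names(seq))
  circ <- stats::setNames(rep(FALSE, length(seq)), names(seq))
  circ[names(circular)[names(circular) %in% names(seq)]] <-
    circular[names(circular) %in% names(seq)]
  structure(list(seq = seq, circular = circ), class = "editome_genome")
}

#' Write a genome object to FASTA
#'
#' @param genome An `editome_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

contig_length <- function(genome, contig) {
  if (!contig %in% names(genome$seq)) stopf("unknown contig: %s", contig)
  nchar(genome$seq[[contig]])
}

# Fetch bases at 0-based positions on the forward strand (with wrap-around on
# circular contigs).
genome_base <- function(genome, contig, pos) {
  L <- contig_length(genome, contig)
  if (isTRUE(genome$circular[[contig]])) pos <- pos %% L
  if (any(pos < 0 | pos >= L)) stopf("position outside contig %s", contig)
  s <- genome$seq[[contig]]
  vapply(pos, function(p) substr(s, p + 1, p + 1), character(1))
}

#' @export
print.editome_genome <- function(x, ...) {
  cat(sprintf("<editome_genome> %d contig(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  for (id in names(x$seq)) {
    cat(sprintf("  %s: %d bp%s\n", id, nchar(x$seq[[id]]),
                if (isTRUE(x$circular[[id]])) " (circular)" else ""))
  }
  invisible(x)
}
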