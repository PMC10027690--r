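#' Caller thresholds for RNA editing site detection
#'
#' Bundles the detection thresholds applied by [call_edits()]. The defaults
#' follow the stringent criteria used for fern organelle editomes: at least
#' 30 RNA reads at the site (edited + unedited) and an editing efficiency of
#' at least 1% in chloroplast mode or 5% in mitochondrial mode. The DNA
#' homogeneity filter (consensus base fraction >= 0.95 at >= 10 DNA reads)
#' excludes paralogous or repeat-collapsed positions where the genomic base
#' itself is ambiguous.
#'
#' @param mode `"chloroplast"`/`"cp"` or `"mitochondrial"`/`"mt"`; selects
#'   the default `min_frequency_percent` (1 vs 5).
#' @param min_rna_reads Minimum RNA reads (edited + reference) at the site.
#' @param min_frequency_percent Minimum editing efficiency in percent;
#'   defaults from `mode`.
#' @param min_dna_reads Minimum DNA reads needed to fix the reference base.
#' @param min_dna_ref_fraction Minimum fraction of DNA reads supporting the
#'   consensus reference base.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(mode = c("chloroplast", "cp", "mitochondrial", "mt"),
                          min_rna_reads = 30L,
                          min_frequency_percent = NULL,
                          min_dna_reads = 10L,
                          min_dna_ref_fraction = 0.95) {
  mode <- match.arg(mode)
  mode <- if (mode %in% c("cp", "chloroplast")) "chloroplast" else "mitochondrial"
  if (is.null(min_frequency_percent))
    min_frequency_percent <- if (mode == "chloroplast") 1.0 else 5.0
  if (min_rna_reads < 1) stopf("min_rna_reads must be >= 1")
  if (min_frequency_percent <= 0 || min_frequency_percent > 100)
    stopf("min_frequency_percent must be in (0, 100]")
  structure(list(mode = mode, min_rna_reads = as.integer(min_rna_reads),
                 min_frequency_percent = min_frequency_percent,
                 min_dna_reads = as.integer(min_dna_reads),
                 min_dna_ref_fraction = min_dna_ref_fraction),
            class = "caller_config")
}

#' Read a per-position base-count table
#'
#' Pileup tables are TSVs with header columns `contig`, `pos` (0-based,
#' forward reference strand), `A`, `C`, `G`, `T`. Rows are returned sorted by
#' (contig, position).
#'
#' @param path TSV file path.
#' @return data.frame with the pileup columns plus `total`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stopf("pileup file not found: %s", path)
  p <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = c(contig = "character"),
                         check.names = FALSE)
  need <- c("contig", "pos", "A", "C", "G", "T")
  if (!all(need %in% names(p)))
    stopf("pileup must have columns %s", paste(need, collapse = ", "))
  for (b in c("pos", "A", "C", "G", "T")) {
    if (!is.numeric(p[[b]])) stopf("pileup column %s is not numeric", b)
  }
  if (any(p$A < 0 | p$C < 0 | p$G < 0 | p$T < 0))
    stopf("pileup contains negative base counts")
  p <- p[order(p$contig, p$pos), , drop = FALSE]
  rownames(p) <- NULL
  p$total <- p$A + p$C + p$G + p$T
  p
}

#' Write a pileup table
#' @param pileup data.frame with columns `contig`, `pos`, `A`, `C`, `G`, `T`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("contig", "pos", "A", "C", "G", "T")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RNA editing efficiency in percent
#'
#' The efficiency of an editing site is the percentage of transcripts edited,
#' estimated as edited reads over (edited + unedited) reads. Reads carrying
#' neither the edited nor the reference base (sequencing errors) are excluded
#' from the denominator so that the estimate isolates the editing signal.
#' Values are reported to three decimal places.
#'
#' @param edited,ref Read counts for the edited and the reference base.
#' @return Numeric percentage, rounded to 3 decimals.
#' @export
editing_efficiency <- function(edited, ref) {
  if (any(edited + ref < 1)) stopf("efficiency undefined: edited + ref reads must be >= 1")
  round(100 * edited / (edited + ref), 3)
}

# The four chemically possible (forward reference base -> strand/type/edited
# forward base) combinations. C-to-U appears as C->T on '+' or G->A on '-';
# U-to-C as T->C on '+' or A->G on '-'.
EDIT_COMBOS <- data.frame(
  ref = c("C", "G", "T", "A"),
  strand = c("+", "-", "+", "-"),
  type = c("CtoU", "CtoU", "UtoC", "UtoC"),
  edited = c("T", "A", "C", "G"),
  stringsAsFactors = FALSE
)

#' Call C-to-U and U-to-C RNA editing sites from paired DNA/RNA pileups
#'
#' For every position present in both pileups, the DNA consensus base is
#' taken as the reference; a site is called when (a) the DNA consensus
#' fraction is at least `min_dna_ref_fraction` at `min_dna_reads` or more DNA
#' reads, (b) the RNA reads at the site (edited + reference base) reach
#' `min_rna_reads`, and (c) the editing efficiency reaches
#' `min_frequency_percent`. Only the four (reference base, strand)
#' combinations that can represent C-to-U or U-to-C editing on the
#' transcribed strand are considered; the strand is taken from the
#' overlapping annotated feature, with unannotated positions evaluated on the
#' single strand their reference base admits and flagged intergenic.
#' Positions whose reference base is N are skipped.
#'
#' @param dna,rna Pileup data.frames (see [read_pileup()]).
#' @param config A [caller_config()].
#' @param genes Optional list of [gene_model()] objects for strand
#'   assignment.
#' @param genome Optional `editome_genome` (needed with `genes`).
#' @param index Optional precomputed [position_index()].
#' @return data.frame of raw calls: `contig`, `pos` (0-based), `strand`,
#'   `type`, `ref_base`, `edited_count`, `ref_count`, `efficiency`,
#'   `intergenic`.
#' @export
call_edits <- function(dna, rna, config = caller_config(), genes = NULL,
                       genome = NULL, index = NULL) {
  if (is.null(index) && !is.null(genes)) {
    if (is.null(genome)) stopf("genome required when genes are supplied")
    index <- position_index(genes, genome)
  }
  if (!"total" %in% names(dna)) dna$total <- dna$A + dna$C + dna$G + dna$T
  if (!"total" %in% names(rna)) rna$total <- rna$A + rna$C + rna$G + rna$T
  m <- merge(dna, rna, by = c("contig", "pos"), suffixes = c(".d", ".r"))
  if (!nrow(m)) return(empty_calls())
  dmat <- as.matrix(m[, c("A.d", "C.d", "G.d", "T.d")])
  bases <- c("A", "C", "G", "T")
  ref_i <- max.col(dmat, ties.method = "first")
  ref <- bases[ref_i]
  dtot <- m$total.d
  dfrac <- dmat[cbind(seq_len(nrow(m)), ref_i)] / pmax(dtot, 1)
  ok_dna <- dtot >= config$min_dna_reads & dfrac >= config$min_dna_ref_fraction
  keep <- which(ok_dna & ref %in% EDIT_COMBOS$ref)
  if (!length(keep)) return(empty_calls())

  # strand from annotation (feature with highest precedence at the position)
  feat_strand <- rep(NA_character_, nrow(m))
  if (!is.null(index) && nrow(index)) {
    key <- paste(m$contig, m$pos)
    idx <- index[order(index$rank), , drop = FALSE]
    idx <- idx[!duplicated(paste(idx$contig, idx$gpos)), , drop = FALSE]
    mm <- match(key, paste(idx$contig, idx$gpos))
    feat_strand <- idx$strand[mm]
  }

  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    combo <- EDIT_COMBOS[EDIT_COMBOS$ref == ref[i], , drop = FALSE]
    annotated <- !is.na(feat_strand[i])
    if (annotated && combo$strand != feat_strand[i]) next
    e_cnt <- m[[paste0(combo$edited, ".r")]][i]
    r_cnt <- m[[paste0(combo$ref, ".r")]][i]
    site_reads <- e_cnt + r_cnt
    if (site_reads < config$min_rna_reads || e_cnt < 1) next
    eff <- 100 * e_cnt / site_reads
    if (eff < config$min_frequency_percent) next
    out[[j]] <- data.frame(contig = m$contig[i], pos = m$pos[i],
                           strand = combo$strand, type = combo$type,
                           ref_base = combo$ref, edited_count = e_cnt,
                           ref_count = r_cnt,
                           efficiency = round(eff, 3),
                           intergenic = !annotated)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(contig = character(0), pos = integer(0), strand = character(0),
             type = character(0), ref_base = character(0),
             edited_count = integer(0), ref_count = integer(0),
             efficiency = numeric(0), intergenic = logical(0))
}
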