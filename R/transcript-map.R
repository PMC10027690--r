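#' Build the transcript coordinate map of a gene
#'
#' Maps every genomic position belonging to a gene to its coordinate in the
#' reported label system:
#' * body positions (CDS or structural RNA) get 1-based transcript positions
#'   counted from the first nucleotide of the mature sequence, concatenated
#'   across exon segments in transcript order (minus-strand segments are read
#'   in reverse-complement orientation);
#' * 5'-UTR positions are negative, with -1 immediately upstream of position
#'   1 and no position 0;
#' * 3'-UTR positions continue the positive transcript numbering past the
#'   last body position, flagged as 3'UTR;
#' * intron interiors map to `(intron name, 1-based offset)`; for trans
#'   introns with annotated part extents the offsets continue cumulatively
#'   from the 5' part into the 3' part.
#'
#' On circular contigs, UTR/intron flanks wrap around the origin; on linear
#' contigs, out-of-bounds flank positions are silently truncated.
#'
#' @param gene A [gene_model()].
#' @param genome An `editome_genome`.
#' @return An object of class `transcript_map` with data.frame components
#'   `$body` (`contig`, `gpos`, `strand`, `tpos`, `region`) and `$intron`
#'   (`contig`, `gpos`, `strand`, `intron`, `offset`), plus `$length` (mature
#'   body length in nt).
#' @export
transcript_map <- function(gene, genome) {
  ex <- gene$exons
  n_ex <- nrow(ex)
  lens <- ex$end - ex$start
  L <- sum(lens)
  for (k in seq_len(n_ex)) {
    if (ex$end[k] > contig_length(genome, ex$contig[k]))
      stopf("gene %s: exon segment beyond contig %s", gene$name, ex$contig[k])
  }
  body <- do.call(rbind, lapply(seq_len(n_ex), function(k) {
    g <- if (ex$strand[k] == "+") seq(ex$start[k], ex$end[k] - 1L)
         else seq(ex$end[k] - 1L, ex$start[k])
    data.frame(contig = ex$contig[k], gpos = g, strand = ex$strand[k])
  }))
  body$tpos <- seq_len(L)
  body$region <- "body"

  # Genomic positions flanking an exon segment, in order of increasing
  # distance from the segment; wraps on circular contigs, truncates on
  # linear ones.
  flank <- function(k, n, upstream) {
    if (n <= 0) return(data.frame(contig = character(0), gpos = integer(0),
                                  strand = character(0)))
    clen <- contig_length(genome, ex$contig[k])
    before_start <- (ex$strand[k] == "+") == upstream
    p <- if (before_start) ex$start[k] - seq_len(n) else ex$end[k] - 1L + seq_len(n)
    if (isTRUE(genome$circular[[ex$contig[k]]])) {
      p <- p %% clen
    } else {
      keep <- p >= 0 & p < clen
      if (!all(keep)) p <- p[seq_len(match(FALSE, keep, nomatch = length(p) + 1L) - 1L)]
    }
    data.frame(contig = ex$contig[k], gpos = p, strand = ex$strand[k])
  }

  u5 <- flank(1L, gene$utr5, upstream = TRUE)
  if (nrow(u5)) { u5$tpos <- -seq_len(nrow(u5)); u5$region <- "5'UTR" }
  u3 <- flank(n_ex, gene$utr3, upstream = FALSE)
  if (nrow(u3)) { u3$tpos <- L + seq_len(nrow(u3)); u3$region <- "3'UTR" }
  body <- rbind(if (nrow(u5)) u5[, names(body)] else NULL, body,
                if (nrow(u3)) u3[, names(body)] else NULL)

  introns <- gene$introns
  imap <- NULL
  if (nrow(introns)) {
    for (k in seq_len(nrow(introns))) {
      if (introns$cis[k]) {
        a <- ex[k, ]; b <- ex[k + 1, ]
        if (a$strand == "+") {
          gap <- b$start - a$end
          if (gap < 0) stopf("gene %s: exon parts out of order on '+' strand", gene$name)
          g <- if (gap > 0) seq(a$end, b$start - 1L) else integer(0)
        } else {
          gap <- a$start - b$end
          if (gap < 0) stopf("gene %s: exon parts out of order on '-' strand", gene$name)
          g <- if (gap > 0) seq(a$start - 1L, b$end) else integer(0)
        }
        if (length(g))
          imap <- rbind(imap, data.frame(contig = a$contig, gpos = g,
                                         strand = a$strand,
                                         intron = introns$name[k],
                                         offset = seq_along(g)))
      } else {
        # trans intron: map each half if its genomic extent is annotated;
        # offsets run cumulatively 5' part then 3' part
        n5 <- introns$len5[k]; n3 <- introns$len3[k]
        off0 <- 0L
        if (!is.na(n5) && n5 > 0) {
          f <- flank(k, as.integer(n5), upstream = FALSE)
          imap <- rbind(imap, data.frame(contig = f$contig, gpos = f$gpos,
                                         strand = f$strand,
                                         intron = introns$name[k],
                                         offset = seq_len(nrow(f))))
          off0 <- as.integer(n5)
        }
        if (!is.na(n3) && n3 > 0) {
          f <- flank(k + 1L, as.integer(n3), upstream = TRUE)
          # flank() orders by distance from the exon; the transcript-order
          # offset within the 3' part increases toward the exon
          f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
          imap <- rbind(imap, data.frame(contig = f$contig, gpos = f$gpos,
                                         strand = f$strand,
                                         intron = introns$name[k],
                                         offset = off0 + seq_len(nrow(f))))
        }
      }
    }
  }
  if (is.null(imap)) imap <- data.frame(contig = character(0), gpos = integer(0),
                                        strand = character(0), intron = character(0),
                                        offset = integer(0))
  structure(list(gene = gene$name, kind = gene$kind, body = body,
                 intron = imap, length = L),
            class = "transcript_map")
}

#' Mature transcript sequence of a gene
#'
#' Concatenates the exon segments in transcript order, reverse-complementing
#' minus-strand segments, i.e. the spliced sequence whose position 1 is
#' transcript position 1.
#'
#' @param gene A [gene_model()].
#' @param genome An `editome_genome`.
#' @return A character scalar (DNA alphabet; the transcript's U is written T).
#' @export
transcript_sequence <- function(gene, genome) {
  ex <- gene$exons
  parts <- vapply(seq_len(nrow(ex)), function(k) {
    s <- substr(genome$seq[[ex$contig[k]]], ex$start[k] + 1L, ex$end[k])
    if (ex$strand[k] == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

codon_at <- function(tx_seq, codon_index) {
  substr(tx_seq, 3L * codon_index - 2L, 3L * codon_index)
}

#' Index all annotated positions of a gene set
#'
#' Builds a lookup table from genomic position to feature context used by
#' [locate_position()] and [call_edits()]. One row per (gene, position)
#' combination; positions covered by several features keep all rows, with a
#' precedence rank (CDS < intron < UTR < rRNA/tRNA) used for the primary
#' location call.
#'
#' @param genes List of [gene_model()] objects.
#' @param genome An `editome_genome`.
#' @return data.frame with columns `contig`, `gpos`, `strand`, `gene`,
#'   `category`, `pos` (transcript position, UTR position or intron offset),
#'   `intron`, `codon_index`, `codon_pos`, `rank`.
#' @export
position_index <- function(genes, genome) {
  rows <- lapply(genes, function(gm) {
    tm <- transcript_map(gm, genome)
    coding <- gm$kind %in% c("CDS", "ORF")
    b <- tm$body
    cat_body <- ifelse(b$region == "body",
                       if (coding) "CDS" else gm$kind,
                       b$region)
    body <- data.frame(contig = b$contig, gpos = b$gpos, strand = b$strand,
                       gene = gm$name, category = cat_body, pos = b$tpos,
                       intron = NA_character_,
                       codon_index = ifelse(coding & b$region == "body",
                                            ceiling(b$tpos / 3), NA_real_),
                       codon_pos = ifelse(coding & b$region == "body",
                                          ((b$tpos - 1L) %% 3L) + 1L, NA_real_))
    i <- tm$intron
    intr <- if (nrow(i)) data.frame(contig = i$contig, gpos = i$gpos,
                                    strand = i$strand, gene = gm$name,
                                    category = "intron", pos = i$offset,
                                    intron = i$intron, codon_index = NA_real_,
                                    codon_pos = NA_real_) else NULL
    rbind(body, intr)
  })
  idx <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rank_of <- c(CDS = 1, intron = 2, `5'UTR` = 3, `3'UTR` = 3, rRNA = 4, tRNA = 4)
  idx$rank <- rank_of[idx$category]
  idx
}

#' Locate a genomic position within the annotation
#'
#' Returns the highest-precedence feature context overlapping a genomic
#' position (precedence CDS > intron > UTR > rRNA/tRNA > intergenic), with
#' codon index and codon position (1-3) for coding positions. All
#' overlapping contexts are available via the `"overlaps"` attribute.
#'
#' @param contig,gpos Contig id and 0-based genomic position.
#' @param genes List of [gene_model()] objects.
#' @param genome An `editome_genome`.
#' @param index Optional precomputed [position_index()].
#' @return One-row data.frame (`category`, `gene`, `pos`, `intron`,
#'   `codon_index`, `codon_pos`, `strand`); `category = "intergenic"` when no
#'   feature overlaps.
#' @export
locate_position <- function(contig, gpos, genes, genome, index = NULL) {
  if (is.null(index)) index <- position_index(genes, genome)
  hit <- index[index$contig == contig & index$gpos == gpos, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(category = "intergenic", gene = NA_character_,
                      pos = NA_real_, intron = NA_character_,
                      codon_index = NA_real_, codon_pos = NA_real_,
                      strand = NA_character_))
  }
  hit <- hit[order(hit$rank), , drop = FALSE]
  out <- hit[1, c("category", "gene", "pos", "intron", "codon_index",
                  "codon_pos", "strand"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlaps") <- hit
  out
}
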