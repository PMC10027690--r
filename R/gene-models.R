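#' Construct a gene model
#'
#' A gene model holds the ordered exon segments of one gene in transcript
#' (5'-to-3') order, the introns between adjacent segments, annotated UTR
#' extents and the genetic code used for translation. Exon segments may lie
#' on different contigs and/or strands, which represents genes whose mature
#' transcript is assembled by trans-splicing.
#'
#' Intron names follow the community convention
#' `<gene>i<preceding exonic nt>g<group>`: the number of transcript
#' nucleotides upstream of the intron followed by the intron group (1 or 2),
#' e.g. `nad1i728g2` for a group II intron after nucleotide 728 of `nad1`, or
#' `rrnLi825g1` for a (possibly trans-spliced) group I intron.
#'
#' @param name Gene name (used as the locus part of editing labels).
#' @param kind Feature kind: `"CDS"`, `"rRNA"`, `"tRNA"` or `"ORF"` (ORFs are
#'   treated as coding for effect classification).
#' @param exons data.frame with columns `contig`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`"+"`/`"-"`), one row per exon
#'   segment in transcript order.
#' @param introns Optional data.frame with one row per adjacent exon pair:
#'   `group` (1 or 2), optional `cis` (logical), optional `len5`/`len3`
#'   (genomic lengths of the two parts of a trans intron; `NA` for cis
#'   introns, whose interior is the genomic gap between the flanking exon
#'   segments).
#' @param utr5,utr3 Annotated 5'/3' UTR extents in nucleotides.
#' @param code_table NCBI genetic code table id (default 1, the standard
#'   code, which covers plant organelle coding sequences).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(name, kind = c("CDS", "rRNA", "tRNA", "ORF"),
                       exons, introns = NULL, utr5 = 0L, utr3 = 0L,
                       code_table = 1L) {
  kind <- match.arg(kind)
  exons <- as.data.frame(exons)
  need <- c("contig", "start", "end", "strand")
  if (!all(need %in% names(exons))) stopf("exons must have columns %s",
                                          paste(need, collapse = ", "))
  if (any(exons$start < 0 | exons$start >= exons$end))
    stopf("gene %s: exon segments must satisfy 0 <= start < end", name)
  if (!all(exons$strand %in% c("+", "-")))
    stopf("gene %s: exon strand must be '+' or '-'", name)
  n_ex <- nrow(exons)
  lens <- exons$end - exons$start
  if (kind %in% c("CDS", "ORF") && sum(lens) < 3)
    stopf("gene %s: coding length below one codon", name)
  # overlapping exon segments within one gene are an annotation error
  if (n_ex > 1) {
    for (i in seq_len(n_ex - 1)) for (j in seq(i + 1, n_ex)) {
      if (exons$contig[i] == exons$contig[j] &&
          exons$start[i] < exons$end[j] && exons$start[j] < exons$end[i])
        stopf("gene %s: overlapping exon segments", name)
    }
  }
  if (n_ex > 1) {
    if (is.null(introns) || nrow(as.data.frame(introns)) != n_ex - 1)
      stopf("gene %s: need exactly %d intron spec(s)", name, n_ex - 1)
    introns <- as.data.frame(introns)
    if (!all(introns$group %in% c(1L, 2L)))
      stopf("gene %s: intron group must be 1 or 2", name)
    preceding <- cumsum(lens)[seq_len(n_ex - 1)]
    if (is.null(introns$cis)) {
      introns$cis <- exons$contig[seq_len(n_ex - 1)] ==
        exons$contig[seq(2, n_ex)]
    }
    introns$preceding <- as.integer(preceding)
    introns$name <- sprintf("%si%dg%d", name, introns$preceding, introns$group)
    if (is.null(introns$len5)) introns$len5 <- NA_real_
    if (is.null(introns$len3)) introns$len3 <- NA_real_
  } else {
    introns <- data.frame(preceding = integer(0), group = integer(0),
                          cis = logical(0), name = character(0),
                          len5 = numeric(0), len3 = numeric(0))
  }
  structure(list(name = name, kind = kind, exons = exons,
                 introns = introns[, c("preceding", "group", "cis", "name",
                                       "len5", "len3")],
                 utr5 = as.integer(utr5), utr3 = as.integer(utr3),
                 code_table = as.integer(code_table)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s), %d exon segment(s), %d intron(s), UTRs %d/%d nt\n",
              x$name, x$kind, nrow(x$exons), nrow(x$introns), x$utr5, x$utr3))
  if (nrow(x$introns)) cat("  introns:", paste(x$introns$name, collapse = ", "), "\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file in the dialect used throughout this package: `gene`
#' features carry the locus name (`ID` or `Name`); `CDS`/`rRNA`/`tRNA`
#' segments reference their gene via `Parent` and, for split genes, carry a
#' `part=<n>` attribute giving transcript order and an `intron_group=<1|2>`
#' attribute naming the group of the intron that follows the segment (absent
#' on the last part). `trans=true` on a part marks the following intron as
#' trans-spliced; optional `intron_len5`/`intron_len3` give the genomic
#' extents of the two halves of a trans intron so that intron-internal
#' coordinates can be mapped. `five_prime_UTR`/`three_prime_UTR` features
#' define UTR extents.
#'
#' @param path GFF3 file path.
#' @param genome An `editome_genome`; referenced contigs must exist.
#' @return A named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (!nrow(g)) stopf("annotation file is empty: %s", path)
  first_chr <- function(x) {
    if (is.list(x)) vapply(x, function(v) if (length(v)) as.character(v[[1]]) else NA_character_, character(1))
    else as.character(x)
  }
  g$Parent1 <- if ("Parent" %in% names(g)) first_chr(g$Parent) else NA_character_
  g$seqid <- as.character(g$seqid)
  g$type <- as.character(g$type)
  bad_contig <- setdiff(unique(g$seqid), names(genome$seq))
  if (length(bad_contig)) stopf("annotation references unknown contig(s): %s",
                                paste(bad_contig, collapse = ", "))

  genes_df <- g[g$type == "gene", , drop = FALSE]
  gene_ids <- first_chr(genes_df$ID) %||% first_chr(genes_df$Name)
  gene_name <- ifelse(!is.na(first_chr(genes_df$Name)) & "Name" %in% names(genes_df),
                      first_chr(genes_df$Name), gene_ids)
  out <- list()
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[i]
    parts <- g[!is.na(g$Parent1) & g$Parent1 == gid &
                 g$type %in% c("CDS", "rRNA", "tRNA"), , drop = FALSE]
    if (!nrow(parts)) next
    kind <- parts$type[1]
    pn <- if ("part" %in% names(parts)) suppressWarnings(as.integer(first_chr(parts$part))) else rep(NA_integer_, nrow(parts))
    if (all(is.na(pn))) pn <- seq_len(nrow(parts))
    if (anyNA(pn) || !setequal(pn, seq_len(nrow(parts))))
      stopf("gene %s: part numbers must be consecutive 1..n", gid)
    parts <- parts[order(pn), , drop = FALSE]
    exons <- data.frame(contig = parts$seqid,
                        start = parts$start - 1L,  # GFF3 is 1-based inclusive
                        end = parts$end,
                        strand = as.character(parts$strand))
    introns <- NULL
    if (nrow(parts) > 1) {
      lead <- parts[-nrow(parts), , drop = FALSE]
      grp <- if ("intron_group" %in% names(parts))
        suppressWarnings(as.integer(first_chr(lead$intron_group))) else rep(NA_integer_, nrow(lead))
      if (anyNA(grp))
        stopf("gene %s: multi-part gene lacks intron_group attribute", gid)
      trans_flag <- if ("trans" %in% names(parts))
        tolower(first_chr(lead$trans)) %in% "true" else rep(FALSE, nrow(lead))
      len5 <- if ("intron_len5" %in% names(parts))
        suppressWarnings(as.numeric(first_chr(lead$intron_len5))) else rep(NA_real_, nrow(lead))
      len3 <- if ("intron_len3" %in% names(parts))
        suppressWarnings(as.numeric(first_chr(lead$intron_len3))) else rep(NA_real_, nrow(lead))
      diff_contig <- exons$contig[-nrow(exons)] != exons$contig[-1]
      introns <- data.frame(group = grp, cis = !(trans_flag | diff_contig),
                            len5 = len5, len3 = len3)
    }
    utr5 <- sum(g$end[!is.na(g$Parent1) & g$Parent1 == gid & g$type == "five_prime_UTR"] -
                  (g$start[!is.na(g$Parent1) & g$Parent1 == gid & g$type == "five_prime_UTR"] - 1L))
    utr3 <- sum(g$end[!is.na(g$Parent1) & g$Parent1 == gid & g$type == "three_prime_UTR"] -
                  (g$start[!is.na(g$Parent1) & g$Parent1 == gid & g$type == "three_prime_UTR"] - 1L))
    tbl <- if ("transl_table" %in% names(genes_df))
      suppressWarnings(as.integer(first_chr(genes_df$transl_table[i]))) else NA_integer_
    out[[gene_name[i]]] <- gene_model(gene_name[i],
                                      kind = if (kind %in% c("CDS")) "CDS" else kind,
                                      exons = exons, introns = introns,
                                      utr5 = utr5, utr3 = utr3,
                                      code_table = if (is.na(tbl)) 1L else tbl)
  }
  if (!length(out)) stopf("no gene models found in %s", path)
  out
}

#' Write gene models to GFF3
#'
#' Emits the GFF3 dialect consumed by [read_annotation()].
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gm in genes) {
    ex <- gm$exons
    span_start <- min(ex$start) + 1L
    span_end <- max(ex$end)
    lines <- c(lines, paste(ex$contig[1], "editome", "gene", span_start, span_end,
                            ".", ex$strand[1], ".",
                            sprintf("ID=%s;Name=%s", gm$name, gm$name), sep = "\t"))
    type <- if (gm$kind %in% c("CDS", "ORF")) "CDS" else gm$kind
    for (k in seq_len(nrow(ex))) {
      attrs <- sprintf("Parent=%s;part=%d", gm$name, k)
      if (k < nrow(ex)) {
        intr <- gm$introns[k, ]
        attrs <- paste0(attrs, sprintf(";intron_group=%d", intr$group))
        if (!intr$cis) {
          attrs <- paste0(attrs, ";trans=true")
          if (!is.na(intr$len5)) attrs <- paste0(attrs, sprintf(";intron_len5=%d", as.integer(intr$len5)))
          if (!is.na(intr$len3)) attrs <- paste0(attrs, sprintf(";intron_len3=%d", as.integer(intr$len3)))
        }
      }
      lines <- c(lines, paste(ex$contig[k], "editome", type, ex$start[k] + 1L,
                              ex$end[k], ".", ex$strand[k], if (type == "CDS") "0" else ".",
                              attrs, sep = "\t"))
    }
    utr_line <- function(n, upstream) {
      if (n <= 0) return(NULL)
      k <- if (upstream) 1L else nrow(ex)
      st <- ex$strand[k]
      before_start <- (st == "+") == upstream
      if (before_start) { s <- ex$start[k] - n; e <- ex$start[k] } else { s <- ex$end[k]; e <- ex$end[k] + n }
      type <- if (upstream) "five_prime_UTR" else "three_prime_UTR"
      paste(ex$contig[k], "editome", type, s + 1L, e, ".", st, ".",
            sprintf("Parent=%s", gm$name), sep = "\t")
    }
    lines <- c(lines, utr_line(gm$utr5, TRUE), utr_line(gm$utr3, FALSE))
  }
  writeLines(lines, path)
  invisible(path)
}
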