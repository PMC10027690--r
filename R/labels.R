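#' Standardized RNA editing event labels
#'
#' Editing events are named `<locus>e<U|C><position><effect>`: the locus
#' (gene or intron name), the nucleotide resulting from editing (`eU` for
#' C-to-U, `eC` for U-to-C), the position in the label coordinate system of
#' [transcript_map()], and — for edits within coding sequence — the codon
#' meaning before and after the edit as two amino-acid letters ('*' for a
#' stop identity).
#'
#' For codons carrying several edits, the label shows the cumulative and
#' individual effect pairs separated by a pipe, `<cumulative>|<individual>`
#' (e.g. a first-position edit of a CCA proline codon that alone gives
#' serine but together with a second-position edit gives leucine is labeled
#' `...PL|PS`). Members that are silent in both the unedited and the fully
#' edited codon context instead take an underline form
#' `<unedited pair>_<fully edited pair>` (e.g. `...PP_FF` for a
#' third-position edit of CCC that is silent whether or not the first two
#' positions are edited). Single-edit codons always use the plain pair, even
#' when silent. Intron edits are positioned by the 1-based offset within the
#' intron, 5'-UTR edits by negative positions (-1 immediately upstream of
#' position 1), and 3'-UTR edits continue the positive transcript numbering
#' past the stop codon.
#'
#' @param gene Gene name (ignored for intron edits).
#' @param type `"CtoU"` or `"UtoC"`.
#' @param category One of `"CDS"`, `"intron"`, `"5'UTR"`, `"3'UTR"`,
#'   `"rRNA"`, `"tRNA"`.
#' @param position Label position (transcript position, negative UTR
#'   position, or intron offset).
#' @param intron Intron name (required for `category = "intron"`).
#' @param ind_pair,cum_pair,ctx_pair Two-letter effect pairs (CDS only): the
#'   individual, cumulative and fully-edited-context pairs from
#'   [classify_codon_edits()].
#' @param multi Logical: does the codon carry more than one edit?
#' @param silent Logical: is this member silent (underline form)?
#' @return The label string.
#' @export
make_edit_label <- function(gene, type, category, position, intron = NULL,
                            ind_pair = NULL, cum_pair = NULL, ctx_pair = NULL,
                            multi = FALSE, silent = FALSE) {
  eX <- paste0("e", edit_letter(type))
  if (category == "intron") {
    if (is.null(intron)) stopf("intron name required for an intron edit label")
    return(paste0(intron, eX, position))
  }
  if (category %in% c("5'UTR", "3'UTR", "rRNA", "tRNA"))
    return(paste0(gene, eX, position))
  if (category != "CDS") stopf("no label convention for category %s", category)
  if (is.null(ind_pair)) stopf("effect pairs required for a CDS edit label")
  suffix <- if (!multi) {
    ind_pair
  } else if (silent) {
    paste0(ind_pair, "_", ctx_pair)
  } else {
    paste0(cum_pair, "|", ind_pair)
  }
  paste0(gene, eX, position, suffix)
}

#' Parse a standardized editing label
#'
#' Recovers the components of a label produced by [make_edit_label()] (or
#' drawn from a published edit table using the same grammar):
#' locus, edit type, position, effect pairs and derived flags. The locus is
#' recognized as an intron when it ends in the `i<number>g<1|2>` intron
#' naming pattern; negative positions are 5'-UTR edits; a label with effect
#' pairs is a coding edit; a pair-less non-negative label is a
#' non-coding-position edit (3'-UTR, rRNA/tRNA or similar), reported as
#' category `"non-CDS"` since the grammar does not distinguish them.
#'
#' @param label Character vector of labels.
#' @return data.frame with columns `label`, `locus`, `gene`, `intron`,
#'   `type`, `position`, `category`, `ind_before`, `ind_after`, `cum_before`,
#'   `cum_after`, `ctx_before`, `ctx_after`, `multi`, `silent`,
#'   `stop_removed`, `stop_created`, `start_created`, `ok` (parse success)
#'   and `error`.
#' @export
parse_edit_label <- function(label) {
  one <- function(lab) {
    bad <- function(msg) data.frame(label = lab, locus = NA_character_,
                                    gene = NA_character_, intron = NA_character_,
                                    type = NA_character_, position = NA_real_,
                                    category = NA_character_,
                                    ind_before = NA_character_, ind_after = NA_character_,
                                    cum_before = NA_character_, cum_after = NA_character_,
                                    ctx_before = NA_character_, ctx_after = NA_character_,
                                    multi = NA, silent = NA, stop_removed = NA,
                                    stop_created = NA, start_created = NA,
                                    ok = FALSE, error = msg)
    m <- regmatches(lab, regexec(
      "^(.+)e([UC])(-?[0-9]+)((?:[A-Z*]{2}\\|[A-Z*]{2})|(?:[A-Z*]{2}_[A-Z*]{2})|(?:[A-Z*]{2}))?$",
      lab))[[1]]
    if (!length(m)) return(bad("label does not match <locus>e<U|C><pos>[<pairs>]"))
    locus <- m[2]
    type <- if (m[3] == "U") "CtoU" else "UtoC"
    pos <- as.numeric(m[4])
    pairs <- m[5]
    is_intron <- grepl("i[0-9]+g[12]$", locus)
    ind <- cum <- ctx <- c(NA_character_, NA_character_)
    multi <- FALSE; silent <- NA
    category <- if (is_intron) "intron" else if (pos < 0) "5'UTR"
                else if (nzchar(pairs)) "CDS" else "non-CDS"
    if (nzchar(pairs)) {
      if (is_intron || pos < 0) return(bad("effect pairs on a non-coding label"))
      if (grepl("\\|", pairs)) {
        halves <- strsplit(pairs, "|", fixed = TRUE)[[1]]
        cum <- strsplit(halves[1], "")[[1]]
        ind <- strsplit(halves[2], "")[[1]]
        multi <- TRUE; silent <- FALSE
      } else if (grepl("_", pairs, fixed = TRUE)) {
        halves <- strsplit(pairs, "_", fixed = TRUE)[[1]]
        ind <- strsplit(halves[1], "")[[1]]
        ctx <- strsplit(halves[2], "")[[1]]
        cum <- ind
        multi <- TRUE; silent <- TRUE
      } else {
        ind <- cum <- strsplit(pairs, "")[[1]]
        silent <- ind[1] == ind[2]
      }
    }
    if (pos == 0) return(bad("position 0 does not exist (UTR numbering is ...,-2,-1)"))
    data.frame(label = lab, locus = locus,
               gene = if (is_intron) sub("i[0-9]+g[12]$", "", locus) else locus,
               intron = if (is_intron) locus else NA_character_,
               type = type, position = pos, category = category,
               ind_before = ind[1], ind_after = ind[2],
               cum_before = cum[1], cum_after = cum[2],
               ctx_before = ctx[1], ctx_after = ctx[2],
               multi = multi, silent = silent,
               stop_removed = identical(ind[1], "*") && !identical(ind[2], "*"),
               stop_created = identical(ind[2], "*") && !identical(ind[1], "*"),
               start_created = category == "CDS" && pos >= 1 && pos <= 3 &&
                 identical(cum[2], "M") && !identical(cum[1], "M"),
               ok = TRUE, error = NA_character_)
  }
  out <- do.call(rbind, lapply(label, one))
  rownames(out) <- NULL
  out
}

#' Re-assemble a label from its parsed components
#'
#' The inverse of [parse_edit_label()]: `format_parsed_label(parse_edit_label(x))`
#' reproduces `x` for every well-formed label.
#'
#' @param parsed data.frame as returned by [parse_edit_label()].
#' @return Character vector of labels.
#' @export
format_parsed_label <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    p <- parsed[i, ]
    if (!isTRUE(p$ok)) return(NA_character_)
    make_edit_label(gene = p$gene, type = p$type,
                    category = if (p$category == "non-CDS") "3'UTR" else p$category,
                    position = if (p$position == as.integer(p$position))
                      as.integer(p$position) else p$position,
                    intron = p$intron,
                    ind_pair = if (is.na(p$ind_before)) NULL else paste0(p$ind_before, p$ind_after),
                    cum_pair = if (is.na(p$cum_before)) NULL else paste0(p$cum_before, p$cum_after),
                    ctx_pair = if (is.na(p$ctx_before)) NULL else paste0(p$ctx_before, p$ctx_after),
                    multi = isTRUE(p$multi), silent = isTRUE(p$silent))
  }, character(1))
}
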