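#' Annotate raw editing calls against gene models
#'
#' Attaches location context, codon-level effects and standardized labels to
#' the raw calls produced by [call_edits()]. Edits falling in the same codon
#' of the same gene are grouped so that individual and cumulative effects can
#' be resolved: the cumulative context applies *all* called edits of the
#' codon regardless of their efficiencies. Calls with no annotation context
#' receive a `contig:position` fallback label and are flagged.
#'
#' @param calls data.frame from [call_edits()] (columns `contig`, `pos`,
#'   `strand`, `type`, `efficiency` at minimum).
#' @param genes List of [gene_model()] objects.
#' @param genome An `editome_genome`.
#' @param index Optional precomputed [position_index()].
#' @return data.frame of annotated edit sites: the call columns plus
#'   `gene`, `category`, `tpos` (label position), `intron`, `codon_index`,
#'   `codon_pos`, `ref_codon`, `ind_before`, `ind_after`, `cum_before`,
#'   `cum_after`, `silent`, `codon_change`, `start_created`, `stop_created`,
#'   `stop_removed`, `multi`, `label`, `unannotated`.
#' @export
annotate_edits <- function(calls, genes, genome, index = NULL) {
  if (is.null(index)) index <- position_index(genes, genome)
  n <- nrow(calls)
  if (!n) return(empty_sites())
  loc <- do.call(rbind, lapply(seq_len(n), function(i) {
    locate_position(calls$contig[i], calls$pos[i], genes, genome, index = index)
  }))
  out <- data.frame(calls,
                    gene = loc$gene, category = loc$category, tpos = loc$pos,
                    intron = loc$intron, codon_index = loc$codon_index,
                    codon_pos = loc$codon_pos,
                    ref_codon = NA_character_,
                    ind_before = NA_character_, ind_after = NA_character_,
                    cum_before = NA_character_, cum_after = NA_character_,
                    silent = NA, codon_change = NA,
                    start_created = FALSE, stop_created = FALSE,
                    stop_removed = FALSE, multi = FALSE,
                    label = NA_character_,
                    unannotated = loc$category == "intergenic")

  # strand consistency: where annotation is available it must agree with the
  # call's strand
  mism <- !out$unannotated & !is.na(loc$strand) & loc$strand != calls$strand
  if (any(mism)) stopf("%d call(s) whose strand disagrees with the annotation", sum(mism))

  tx_cache <- new.env(parent = emptyenv())
  tx_of <- function(gname) {
    if (is.null(tx_cache[[gname]]))
      tx_cache[[gname]] <- transcript_sequence(genes[[gname]], genome)
    tx_cache[[gname]]
  }

  is_cds <- which(out$category == "CDS")
  if (length(is_cds)) {
    grp <- split(is_cds, paste(out$gene[is_cds], out$codon_index[is_cds]))
    for (rows in grp) {
      g <- out$gene[rows[1]]
      code <- genetic_code_for(genes[[g]]$code_table)
      cdn <- codon_at(tx_of(g), out$codon_index[rows[1]])
      ord <- order(out$codon_pos[rows])
      rows <- rows[ord]
      cls <- classify_codon_edits(cdn, out$codon_pos[rows], out$type[rows],
                                  code = code)
      multi <- length(rows) > 1
      for (k in seq_along(rows)) {
        i <- rows[k]
        out$ref_codon[i] <- cdn
        out$ind_before[i] <- cls$ind_before[k]; out$ind_after[i] <- cls$ind_after[k]
        out$cum_before[i] <- cls$cum_before[k]; out$cum_after[i] <- cls$cum_after[k]
        out$silent[i] <- cls$silent[k]
        out$codon_change[i] <- !cls$silent[k]
        out$stop_removed[i] <- cls$stop_removed[k]
        out$stop_created[i] <- cls$stop_created[k]
        out$start_created[i] <- cls$start_created[k] && out$codon_index[i] == 1
        out$multi[i] <- multi
        out$label[i] <- make_edit_label(
          gene = g, type = out$type[i], category = "CDS",
          position = out$tpos[i],
          ind_pair = paste0(cls$ind_before[k], cls$ind_after[k]),
          cum_pair = paste0(cls$cum_before[k], cls$cum_after[k]),
          ctx_pair = paste0(cls$ctx_before[k], cls$ctx_after[k]),
          multi = multi, silent = cls$silent[k])
      }
    }
  }
  other <- which(!out$unannotated & out$category != "CDS")
  for (i in other) {
    pos_lab <- if (out$category[i] == "5'UTR") -abs(out$tpos[i]) else out$tpos[i]
    out$label[i] <- make_edit_label(gene = out$gene[i], type = out$type[i],
                                    category = out$category[i],
                                    position = pos_lab, intron = out$intron[i])
  }
  unk <- which(out$unannotated)
  for (i in unk) {
    out$label[i] <- sprintf("%s:%de%s", out$contig[i], out$pos[i] + 1L,
                            edit_letter(out$type[i]))
  }
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  cbind(empty_calls(),
        data.frame(gene = character(0), category = character(0),
                   tpos = numeric(0), intron = character(0),
                   codon_index = numeric(0), codon_pos = numeric(0),
                   ref_codon = character(0),
                   ind_before = character(0), ind_after = character(0),
                   cum_before = character(0), cum_after = character(0),
                   silent = logical(0), codon_change = logical(0),
                   start_created = logical(0), stop_created = logical(0),
                   stop_removed = logical(0), multi = logical(0),
                   label = character(0), unannotated = logical(0)))
}
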