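#' Summarize an annotated editome
#'
#' Computes the descriptive statistics used to characterize an organelle
#' editome: totals by edit type (C-to-U vs U-to-C), counts by location
#' category, counts by codon effect, unweighted mean editing efficiency per
#' (category x type) cell, and the number of neighboring-silent-edit sites
#' (NESIs, see [find_nesi()]). Every edit is counted exactly once in the
#' location partition.
#'
#' @param sites Annotated edit table ([annotate_edits()] or
#'   [ingest_supplementary()]).
#' @param nesi_window NESI window in transcript nucleotides.
#' @return A list of class `editome_summary` with components `$total`,
#'   `$by_type`, `$by_category` (type x category count table),
#'   `$by_effect` (type x effect count table), `$mean_efficiency`
#'   (category x type means), and `$nesi` (NESI count).
#' @export
summarize_editome <- function(sites, nesi_window = 3) {
  types <- c("CtoU", "UtoC")
  cats <- c("CDS", "intron", "5'UTR", "3'UTR", "rRNA", "tRNA", "non-CDS",
            "intergenic")
  n <- nrow(sites)
  by_type <- stats::setNames(vapply(types, function(t) sum(sites$type == t), 0), types)
  cat_f <- factor(sites$category, levels = cats)
  type_f <- factor(sites$type, levels = types)
  by_category <- table(type = type_f, category = cat_f)
  effects <- c("codon_change", "silent", "start_created", "stop_created",
               "stop_removed")
  by_effect <- sapply(effects, function(e) {
    v <- sites[[e]]
    vapply(types, function(t) sum(v & sites$type == t, na.rm = TRUE), 0)
  })
  if (n == 0) by_effect <- matrix(0, 2, length(effects),
                                  dimnames = list(types, effects))
  mean_eff <- tapply(sites$efficiency, list(cat_f, type_f), mean)
  nesi <- find_nesi(sites, window = nesi_window)
  structure(list(total = n, by_type = by_type,
                 by_category = by_category, by_effect = by_effect,
                 mean_efficiency = mean_eff, nesi = nrow(nesi),
                 nesi_pairs = nesi),
            class = "editome_summary")
}

#' @export
print.editome_summary <- function(x, ...) {
  cat(sprintf("Editome summary: %d edits (%d C-to-U, %d U-to-C)\n",
              x$total, x$by_type[["CtoU"]], x$by_type[["UtoC"]]))
  cat("\nBy location:\n"); print(x$by_category)
  cat("\nBy effect:\n"); print(x$by_effect)
  cat("\nMean efficiency (%):\n")
  print(round(x$mean_efficiency[rowSums(!is.na(x$mean_efficiency)) > 0, ,
                                drop = FALSE], 1))
  cat(sprintf("\nNESIs (silent edits neighboring non-silent ones): %d\n", x$nesi))
  invisible(x)
}

#' Count start/stop codon events by edit type
#'
#' Tallies creations of start codons, creations of stop codons and removals
#' of stop codons, separately for C-to-U and U-to-C edits.
#'
#' @param sites Annotated edit table.
#' @return data.frame with columns `type`, `start_created`, `stop_created`,
#'   `stop_removed`.
#' @export
count_stop_start_events <- function(sites) {
  types <- c("CtoU", "UtoC")
  do.call(rbind, lapply(types, function(t) {
    s <- sites[sites$type == t, , drop = FALSE]
    data.frame(type = t,
               start_created = sum(s$start_created, na.rm = TRUE),
               stop_created = sum(s$stop_created, na.rm = TRUE),
               stop_removed = sum(s$stop_removed, na.rm = TRUE))
  }))
}

#' Find neighboring-silent-edit sites (NESIs)
#'
#' A silent coding edit is a NESI when a non-silent edit of the same gene
#' lies within `window` transcript nucleotides. The default window of 3
#' captures edits in the same or an immediately adjacent codon region.
#'
#' @param sites Annotated edit table (needs `gene`, `category`, `tpos`,
#'   `silent`).
#' @param window Maximum transcript distance in nucleotides.
#' @return data.frame with one row per NESI: `silent_label`, `partner_label`,
#'   `gene`, `distance` (to the nearest non-silent edit).
#' @export
find_nesi <- function(sites, window = 3) {
  empty <- data.frame(silent_label = character(0), partner_label = character(0),
                      gene = character(0), distance = numeric(0))
  if (!nrow(sites)) return(empty)
  cds <- sites[sites$category == "CDS" & !is.na(sites$silent), , drop = FALSE]
  sil <- cds[cds$silent, , drop = FALSE]
  non <- cds[!cds$silent, , drop = FALSE]
  if (!nrow(sil) || !nrow(non)) return(empty)
  out <- lapply(seq_len(nrow(sil)), function(i) {
    cand <- non[non$gene == sil$gene[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    d <- abs(cand$tpos - sil$tpos[i])
    j <- which.min(d)
    if (d[j] > window) return(NULL)
    data.frame(silent_label = sil$label[i], partner_label = cand$label[j],
               gene = sil$gene[i], distance = d[j])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean editing efficiency by an arbitrary grouping column
#'
#' Unweighted arithmetic mean of per-site efficiency percentages per group
#' (e.g. by location category, or by an editing-prediction class column
#' carried in from an ingested table).
#'
#' @param sites Annotated edit table.
#' @param by Name of the grouping column.
#' @return data.frame with columns `group`, `n`, `mean_efficiency`.
#' @export
mean_efficiency_by <- function(sites, by = "category") {
  if (!by %in% names(sites)) stopf("unknown grouping column: %s", by)
  g <- sites[[by]]
  groups <- sort(unique(g[!is.na(g)]))
  out <- do.call(rbind, lapply(groups, function(gr) {
    e <- sites$efficiency[!is.na(g) & g == gr]
    data.frame(group = gr, n = length(e), mean_efficiency = mean(e))
  }))
  if (is.null(out)) out <- data.frame(group = character(0), n = integer(0),
                                      mean_efficiency = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write an editome summary as a long-format TSV
#'
#' @param summary An `editome_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  rows <- list(data.frame(section = "total", type = "all", key = "edits",
                          value = summary$total))
  for (t in names(summary$by_type))
    rows <- c(rows, list(data.frame(section = "by_type", type = t,
                                    key = "edits", value = summary$by_type[[t]])))
  bc <- as.data.frame(summary$by_category)
  rows <- c(rows, list(data.frame(section = "by_category", type = bc$type,
                                  key = bc$category, value = bc$Freq)))
  be <- summary$by_effect
  for (t in rownames(be)) for (e in colnames(be))
    rows <- c(rows, list(data.frame(section = "by_effect", type = t, key = e,
                                    value = be[t, e])))
  me <- summary$mean_efficiency
  for (cc in rownames(me)) for (t in colnames(me)) if (!is.na(me[cc, t]))
    rows <- c(rows, list(data.frame(section = "mean_efficiency", type = t,
                                    key = cc, value = round(me[cc, t], 3))))
  rows <- c(rows, list(data.frame(section = "nesi", type = "all", key = "pairs",
                                  value = summary$nesi)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
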