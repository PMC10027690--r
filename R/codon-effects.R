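#' Apply C-to-U / U-to-C edits to a codon
#'
#' Returns the codon obtained by applying the listed edits: C-to-U replaces a
#' C by T, U-to-C replaces a T by C (transcripts are represented in DNA
#' alphabet). An edit whose type is incompatible with the base at its codon
#' position is a consistency error.
#'
#' @param codon 3-nt character scalar.
#' @param positions Integer vector of codon positions (subset of 1:3).
#' @param types Character vector (`"CtoU"`/`"UtoC"`), recycled to
#'   `length(positions)`.
#' @return The edited codon.
#' @export
apply_codon_edits <- function(codon, positions, types) {
  if (nchar(codon) != 3) stopf("codon must have 3 nucleotides")
  if (length(positions) == 0) return(codon)
  if (!all(positions %in% 1:3)) stopf("codon positions must be in 1:3")
  if (anyDuplicated(positions)) stopf("duplicate codon positions")
  types <- rep_len(types, length(positions))
  out <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (k in seq_along(positions)) {
    p <- positions[k]
    if (types[k] == "CtoU") {
      if (out[p] != "C") stopf("C-to-U edit at codon position %d but base is %s", p, out[p])
      out[p] <- "T"
    } else if (types[k] == "UtoC") {
      if (out[p] != "T") stopf("U-to-C edit at codon position %d but base is %s", p, out[p])
      out[p] <- "C"
    } else stopf("unknown edit type: %s", types[k])
  }
  paste(out, collapse = "")
}

#' Classify the amino-acid effects of all edits sharing one codon
#'
#' For each member edit of a codon, computes:
#' * the individual pair: amino acid of the reference codon vs. the codon
#'   with this edit applied alone;
#' * the cumulative pair: reference amino acid vs. the fully edited codon
#'   (all member edits applied);
#' * the fully-edited-context pair: the codon with all *other* member edits
#'   applied, vs. the fully edited codon — the effect of this edit on an
#'   already otherwise-edited transcript;
#' * effect flags. An edit is `silent` when it changes the amino acid neither
#'   in the unedited nor in the fully edited context. `stop_removed` /
#'   `stop_created` refer to the individual effect ('*' denotes a stop
#'   identity); `start_created` marks a codon that is not ATG but becomes ATG
#'   when fully edited (meaningful at codon 1).
#'
#' @param codon Reference (genomic) codon, 3 nt.
#' @param positions Codon positions (1-3) of the member edits.
#' @param types Edit types, recycled.
#' @param code Genetic code vector as returned by
#'   [Biostrings::getGeneticCode()].
#' @return data.frame with one row per member: `position`, `type`,
#'   `ind_before`, `ind_after`, `cum_before`, `cum_after`, `ctx_before`,
#'   `ctx_after`, `silent`, `stop_removed`, `stop_created`, `start_created`,
#'   plus attribute `"fully_edited"` (the fully edited codon).
#' @export
classify_codon_edits <- function(codon, positions, types,
                                 code = genetic_code_for(1L)) {
  types <- rep_len(types, length(positions))
  full <- apply_codon_edits(codon, positions, types)
  ref_aa <- aa_of(codon, code)
  full_aa <- aa_of(full, code)
  rows <- lapply(seq_along(positions), function(k) {
    alone <- apply_codon_edits(codon, positions[k], types[k])
    others <- if (length(positions) > 1)
      apply_codon_edits(codon, positions[-k], types[-k]) else codon
    ind_aa <- aa_of(alone, code)
    ctx_before <- aa_of(others, code)
    data.frame(position = positions[k], type = types[k],
               ind_before = ref_aa, ind_after = ind_aa,
               cum_before = ref_aa, cum_after = full_aa,
               ctx_before = ctx_before, ctx_after = full_aa,
               silent = (ind_aa == ref_aa) && (full_aa == ctx_before),
               stop_removed = (ref_aa == "*") && (ind_aa != "*"),
               stop_created = (ind_aa == "*") && (ref_aa != "*"),
               start_created = (codon != "ATG") && (full == "ATG"))
  })
  out <- do.call(rbind, rows)
  attr(out, "fully_edited") <- full
  out
}
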