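#' Run the full editome pipeline on one sample
#'
#' Reads genome, annotation and paired DNA/RNA pileups, calls editing sites
#' with the mode-appropriate thresholds, annotates and labels them, and
#' computes the editome summary. All outputs are deterministic functions of
#' the inputs; when `out_dir` is given, the edit table (TSV), the summary
#' (long-format TSV) and a parameter log are written there.
#'
#' @param genome_path FASTA path (or an `editome_genome`).
#' @param annotation_path GFF3 path (or a list of [gene_model()]).
#' @param dna_path,rna_path Pileup TSV paths (or pileup data.frames).
#' @param mode `"cp"`/`"chloroplast"` or `"mt"`/`"mitochondrial"`; selects
#'   the default efficiency threshold (1% vs 5%).
#' @param config Optional [caller_config()] overriding the mode defaults.
#' @param nesi_window NESI window in transcript nt.
#' @param out_dir Optional output directory.
#' @return A list of class `editome_run` with `$calls`, `$sites`, `$summary`
#'   and `$config`.
#' @export
run_editome <- function(genome_path, annotation_path, dna_path, rna_path,
                        mode = c("mt", "mitochondrial", "cp", "chloroplast"),
                        config = NULL, nesi_window = 3, out_dir = NULL) {
  mode <- match.arg(mode)
  mode <- if (mode %in% c("cp", "chloroplast")) "chloroplast" else "mitochondrial"
  if (is.null(config)) config <- caller_config(mode = mode)
  gen <- if (inherits(genome_path, "editome_genome")) genome_path
         else read_genome_fasta(genome_path)
  genes <- if (is.list(annotation_path) && !is.data.frame(annotation_path) &&
                 all(vapply(annotation_path, inherits, logical(1), "gene_model")))
    annotation_path else read_annotation(annotation_path, gen)
  dna <- if (is.data.frame(dna_path)) dna_path else read_pileup(dna_path)
  rna <- if (is.data.frame(rna_path)) rna_path else read_pileup(rna_path)
  idx <- position_index(genes, gen)
  calls <- call_edits(dna, rna, config = config, index = idx)
  sites <- annotate_edits(calls, genes, gen, index = idx)
  summ <- summarize_editome(sites, nesi_window = nesi_window)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sites, file.path(out_dir, "edits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_summary_tsv(summ, file.path(out_dir, "summary.tsv"))
    writeLines(c(
      sprintf("editome %s", as.character(utils::packageVersion("editome"))),
      sprintf("mode: %s", config$mode),
      sprintf("min_rna_reads: %d", config$min_rna_reads),
      sprintf("min_frequency_percent: %g", config$min_frequency_percent),
      sprintf("min_dna_reads: %d", config$min_dna_reads),
      sprintf("min_dna_ref_fraction: %g", config$min_dna_ref_fraction),
      sprintf("nesi_window: %g", nesi_window),
      sprintf("positions_in_both_pileups: %d",
              nrow(merge(dna[, c("contig", "pos")], rna[, c("contig", "pos")]))),
      sprintf("calls: %d", nrow(calls)),
      sprintf("annotated_sites: %d", sum(!sites$unannotated))),
      file.path(out_dir, "run.log"))
  }
  structure(list(calls = calls, sites = sites, summary = summ,
                 config = config), class = "editome_run")
}

#' Ingest a published edit table by parsing its labels
#'
#' Reads a supplementary-style edit table — at minimum a `label` column plus
#' an `efficiency` column (percent) — and reconstructs an annotated edit
#' site table by parsing the standardized labels. Rows whose labels fail to
#' parse are reported in the `"rejects"` attribute rather than dropped
#' silently. Any further columns (e.g. a prediction-class column) are
#' carried through for use with [mean_efficiency_by()].
#'
#' @param table Path to a TSV, or a data.frame.
#' @param label_col,efficiency_col Column names.
#' @return data.frame of edit sites usable with [summarize_editome()], with
#'   attribute `"rejects"` (data.frame of unparseable rows and reasons).
#' @export
ingest_supplementary <- function(table, label_col = "label",
                                 efficiency_col = "efficiency") {
  tab <- if (is.data.frame(table)) table
         else utils::read.delim(table, header = TRUE, sep = "\t")
  if (!label_col %in% names(tab))
    stopf("no '%s' column; columns present: %s", label_col,
          paste(names(tab), collapse = ", "))
  parsed <- parse_edit_label(as.character(tab[[label_col]]))
  eff <- if (efficiency_col %in% names(tab)) as.numeric(tab[[efficiency_col]])
         else rep(NA_real_, nrow(tab))
  keep <- parsed$ok
  sites <- data.frame(label = parsed$label[keep], gene = parsed$gene[keep],
                      intron = parsed$intron[keep], type = parsed$type[keep],
                      category = parsed$category[keep],
                      tpos = parsed$position[keep],
                      efficiency = eff[keep],
                      ind_before = parsed$ind_before[keep],
                      ind_after = parsed$ind_after[keep],
                      cum_before = parsed$cum_before[keep],
                      cum_after = parsed$cum_after[keep],
                      multi = parsed$multi[keep], silent = parsed$silent[keep],
                      codon_change = parsed$category[keep] == "CDS" &
                        !isTRUE_vec(parsed$silent[keep]),
                      start_created = parsed$start_created[keep],
                      stop_created = parsed$stop_created[keep],
                      stop_removed = parsed$stop_removed[keep])
  extra <- setdiff(names(tab), c(label_col, efficiency_col))
  for (cc in extra) sites[[cc]] <- tab[[cc]][keep]
  rejects <- data.frame(row = which(!keep),
                        label = as.character(tab[[label_col]])[!keep],
                        error = parsed$error[!keep])
  attr(sites, "rejects") <- rejects
  sites
}

isTRUE_vec <- function(x) !is.na(x) & x
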