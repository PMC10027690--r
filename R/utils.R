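# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate a single codon under a Biostrings-style genetic code vector.
# Codons containing anything outside ACGT translate to "X".
aa_of <- function(codon, code) {
  if (!grepl("^[ACGT]{3}$", codon)) return("X")
  unname(code[[codon]])
}

genetic_code_for <- function(table_id = 1L) {
  Biostrings::getGeneticCode(as.character(table_id))
}

edit_letter <- function(type) c(CtoU = "U", UtoC = "C")[[type]]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
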