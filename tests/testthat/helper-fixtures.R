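# Fixture builders shared across the test files. Everything is constructed
# in code; no data files are read.

# A single gene on its own contig, plus strand, with optional 5'/3' UTRs and
# one intron after `intron_after` exonic nucleotides. Returns the gene model
# together with a genome containing just its contig.
make_gene_fixture <- function(name, codons, utr5 = 0L, utr3 = 0L,
                              intron_after = NA, intron_len = 0L, group = 2L,
                              utr5_seq = NULL, intron_seq = NULL,
                              pad = 20L, contig = paste0("ctg_", name)) {
  cds <- paste(codons, collapse = "")
  L <- nchar(cds)
  if (is.null(utr5_seq)) utr5_seq <- strrep("A", utr5)
  utr3_seq <- strrep("A", utr3)
  if (!is.na(intron_after)) {
    if (is.null(intron_seq)) intron_seq <- strrep("G", intron_len)
    intron_len <- nchar(intron_seq)
    exon1 <- substr(cds, 1, intron_after)
    exon2 <- substr(cds, intron_after + 1, L)
    seq <- paste0(strrep("A", pad), utr5_seq, exon1, intron_seq, exon2,
                  utr3_seq, strrep("A", pad))
    exons <- data.frame(contig = contig,
                        start = c(pad + utr5, pad + utr5 + intron_after + intron_len),
                        end = c(pad + utr5 + intron_after,
                                pad + utr5 + intron_after + intron_len + (L - intron_after)),
                        strand = "+")
    introns <- data.frame(group = group, cis = TRUE)
  } else {
    seq <- paste0(strrep("A", pad), utr5_seq, cds, utr3_seq, strrep("A", pad))
    exons <- data.frame(contig = contig, start = pad + utr5,
                        end = pad + utr5 + L, strand = "+")
    introns <- NULL
  }
  gen <- genome(stats::setNames(seq, contig))
  gm <- gene_model(name, kind = "CDS", exons = exons, introns = introns,
                   utr5 = utr5, utr3 = utr3)
  list(genome = gen, gene = gm)
}

# Merge several single-gene fixtures into one multi-contig genome + gene list
merge_fixtures <- function(...) {
  fx <- list(...)
  seqs <- unlist(lapply(fx, function(f) f$genome$seq))
  genes <- lapply(fx, function(f) f$gene)
  names(genes) <- vapply(genes, function(g) g$name, character(1))
  list(genome = genome(seqs), genes = genes)
}

# genomic position of a transcript position / intron offset
gpos_at <- function(gene, gen, tpos = NULL, intron_offset = NULL) {
  tm <- transcript_map(gene, gen)
  if (!is.null(tpos)) {
    row <- tm$body[tm$body$tpos == tpos, ]
  } else {
    row <- tm$intron[tm$intron$offset == intron_offset, ]
  }
  stopifnot(nrow(row) == 1)
  list(contig = row$contig, pos = row$gpos, strand = row$strand)
}

# a raw call row at a transcript/intron position of a fixture gene
call_at <- function(gene, gen, type, tpos = NULL, intron_offset = NULL,
                    edited = 90L, ref = 10L) {
  w <- gpos_at(gene, gen, tpos, intron_offset)
  data.frame(contig = w$contig, pos = w$pos, strand = w$strand, type = type,
             ref_base = if (type == "CtoU") {
               if (w$strand == "+") "C" else "G"
             } else {
               if (w$strand == "+") "T" else "A"
             },
             edited_count = edited, ref_count = ref,
             efficiency = editing_efficiency(edited, ref),
             intergenic = FALSE)
}

# The constructed gene contexts behind the worked-example labels: one
# photosystem gene with a high-efficiency S->L edit, stop-removal and
# stop-creation cases, a 5'-UTR edit right upstream of a start codon, an
# intron edit, and the two multi-edit proline codons.
worked_examples <- function() {
  filler <- function(n) rep("GGT", n)
  psbB <- make_gene_fixture("psbB", c("ATG", filler(37), "TCA", filler(2)))
  rpoC2 <- make_gene_fixture("rpoC2", c("ATG", filler(76), "TAA", filler(2)))
  rps2 <- make_gene_fixture("rps2", c("ATG", filler(115), "CGA", filler(2)))
  accD <- make_gene_fixture("accD", c("ATG", filler(5)), utr5 = 10L,
                            utr5_seq = paste0(strrep("A", 9), "C"))
  petB <- make_gene_fixture("petB", c("ATG", "GGT", filler(4)),
                            intron_after = 6L,
                            intron_seq = paste0(strrep("G", 477), "C",
                                                strrep("G", 22)),
                            group = 2L)
  atpB <- make_gene_fixture("atpB", c("ATG", filler(459), "CCA", filler(2)))
  rpoB <- make_gene_fixture("rpoB", c("ATG", filler(219), "CCC", filler(2)))
  all <- merge_fixtures(psbB, rpoC2, rps2, accD, petB, atpB, rpoB)
  calls <- rbind(
    call_at(psbB$gene, all$genome, "CtoU", tpos = 116, edited = 991, ref = 9),
    call_at(rpoC2$gene, all$genome, "UtoC", tpos = 232, edited = 17, ref = 83),
    call_at(rps2$gene, all$genome, "CtoU", tpos = 349, edited = 1, ref = 99),
    call_at(accD$gene, all$genome, "CtoU", tpos = -1),
    call_at(petB$gene, all$genome, "CtoU", intron_offset = 478, edited = 94, ref = 6),
    call_at(atpB$gene, all$genome, "CtoU", tpos = 1381, edited = 979, ref = 21),
    call_at(atpB$gene, all$genome, "CtoU", tpos = 1382, edited = 17, ref = 983),
    call_at(rpoB$gene, all$genome, "CtoU", tpos = 661, edited = 12, ref = 988),
    call_at(rpoB$gene, all$genome, "CtoU", tpos = 662, edited = 663, ref = 337),
    call_at(rpoB$gene, all$genome, "CtoU", tpos = 663, edited = 360, ref = 640))
  expected <- c("psbBeU116SL", "rpoC2eC232*Q", "rps2eU349R*", "accDeU-1",
                "petBi6g2eU478", "atpBeU1381PL|PS", "atpBeU1382PL|PL",
                "rpoBeU661PF|PS", "rpoBeU662PF|PL", "rpoBeU663PP_FF")
  list(genome = all$genome, genes = all$genes, calls = calls,
       expected = expected)
}

# random well-formed labels spanning every branch of the grammar, for
# parse/format round-trip fuzzing
random_labels <- function(n) {
  aa <- c(LETTERS[1:20], "*")
  gene_name <- function() paste0(
    paste(sample(letters, sample(3:5, 1), replace = TRUE), collapse = ""),
    if (stats::runif(1) < 0.4) sample(1:9, 1) else "")
  vapply(seq_len(n), function(i) {
    g <- gene_name()
    kind <- sample(c("cds1", "cds_multi", "cds_silent", "intron", "utr5",
                     "noncds"), 1)
    type <- sample(c("CtoU", "UtoC"), 1)
    if (kind == "intron") {
      make_edit_label(g, type, "intron", sample(1:3000, 1),
                      intron = sprintf("%si%dg%d", g, sample(1:2000, 1),
                                       sample(1:2, 1)))
    } else if (kind == "utr5") {
      make_edit_label(g, type, "5'UTR", -sample(1:200, 1))
    } else if (kind == "noncds") {
      make_edit_label(g, type, "3'UTR", sample(1:3000, 1))
    } else if (kind == "cds1") {
      make_edit_label(g, type, "CDS", sample(1:3000, 1),
                      ind_pair = paste(sample(aa, 2, replace = TRUE), collapse = ""))
    } else if (kind == "cds_multi") {
      make_edit_label(g, type, "CDS", sample(1:3000, 1),
                      ind_pair = paste(sample(aa, 2, replace = TRUE), collapse = ""),
                      cum_pair = paste(sample(aa, 2, replace = TRUE), collapse = ""),
                      multi = TRUE, silent = FALSE)
    } else {
      a <- sample(aa[aa != "*"], 1); b <- sample(aa[aa != "*"], 1)
      make_edit_label(g, type, "CDS", sample(1:3000, 1),
                      ind_pair = paste0(a, a), ctx_pair = paste0(b, b),
                      multi = TRUE, silent = TRUE)
    }
  }, character(1))
}
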