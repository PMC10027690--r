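test_that("FASTA reading preserves lengths, normalizes case and rejects bad alphabets", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 first contig", strrep("ACGTACGTAC", 10),
               ">c2", tolower(strrep("acgta", 10))), f)
  gen <- read_genome_fasta(f)
  expect_equal(unname(nchar(gen$seq)), c(100L, 50L))
  expect_equal(substr(gen$seq[["c2"]], 1, 5), "ACGTA")

  writeLines(c(">c1", "ACGTX"), f)
  expect_error(read_genome_fasta(f), "illegal characters")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), f)
  expect_error(read_genome_fasta(f), "duplicate")
})

test_that("GFF3 parsing builds intron names from exon structure", {
  f <- withr::local_tempfile(fileext = ".gff3")
  gen <- genome(c(cA = strrep("ACGT", 800), cB = strrep("ACGT", 500)))
  writeLines(c(
    "##gff-version 3",
    # single-exon CDS of 300 nt
    "cA\tx\tgene\t11\t310\t.\t+\t.\tID=atp1;Name=atp1",
    "cA\tx\tCDS\t11\t310\t.\t+\t0\tParent=atp1",
    # two cis exon parts, first part 728 nt, group II intron
    "cA\tx\tgene\t401\t1700\t.\t+\t.\tID=nad1;Name=nad1",
    "cA\tx\tCDS\t401\t1128\t.\t+\t0\tParent=nad1;part=1;intron_group=2",
    "cA\tx\tCDS\t1601\t1700\t.\t+\t0\tParent=nad1;part=2",
    # rRNA split over two contigs: a trans-spliced group I intron after 825 nt
    "cA\tx\tgene\t1801\t2625\t.\t+\t.\tID=rrnL;Name=rrnL",
    "cA\tx\trRNA\t1801\t2625\t.\t+\t.\tParent=rrnL;part=1;intron_group=1;trans=true",
    "cB\tx\trRNA\t101\t108\t.\t+\t.\tParent=rrnL;part=2"), f)
  genes <- read_annotation(f, gen)

  expect_equal(nrow(genes$atp1$introns), 0)
  expect_equal(genes$nad1$introns$name, "nad1i728g2")
  expect_true(genes$nad1$introns$cis)
  expect_equal(genes$rrnL$introns$name, "rrnLi825g1")
  expect_false(genes$rrnL$introns$cis)
  expect_equal(genes$rrnL$kind, "rRNA")
  # the tiny 8-nt second exon survives
  expect_equal(diff(unlist(genes$rrnL$exons[2, c("start", "end")])),
               c(end = 8))
})

test_that("annotation errors are reported", {
  gen <- genome(c(cA = strrep("ACGT", 500)))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "cA\tx\tgene\t1\t400\t.\t+\t.\tID=g1",
    "cA\tx\tCDS\t1\t100\t.\t+\t0\tParent=g1;part=1",
    "cA\tx\tCDS\t201\t400\t.\t+\t0\tParent=g1;part=2"), f)
  expect_error(read_annotation(f, gen), "intron_group")
  writeLines(c(
    "##gff-version 3",
    "cA\tx\tgene\t1\t400\t.\t+\t.\tID=g1",
    "cA\tx\tCDS\t1\t100\t.\t+\t0\tParent=g1;part=1;intron_group=2",
    "cA\tx\tCDS\t201\t400\t.\t+\t0\tParent=g1;part=3"), f)
  expect_error(read_annotation(f, gen), "consecutive")
})

test_that("transcript coordinates: body, negative 5'-UTR, intron offsets", {
  fx <- make_gene_fixture("gA", c("ATG", rep("GGT", 9)), utr5 = 5L,
                          pad = 1000L)
  tm <- transcript_map(fx$gene, fx$genome)
  expect_equal(tm$body$gpos[tm$body$tpos == 1], 1005)
  # immediately 5' of the start codon is -1, no position 0
  expect_equal(tm$body$tpos[tm$body$gpos == 1004], -1)
  expect_false(0 %in% tm$body$tpos)

  petB <- make_gene_fixture("petB", c("ATG", "GGT", rep("GGT", 4)),
                            intron_after = 6L, intron_len = 500L, group = 2L)
  tmi <- transcript_map(petB$gene, petB$genome)
  first_intron_nt <- tmi$intron[tmi$intron$offset == 1, ]
  expect_equal(first_intron_nt$intron, "petBi6g2")
  # the intron starts right after exonic genomic position of tpos 6
  expect_equal(first_intron_nt$gpos,
               tmi$body$gpos[tmi$body$tpos == 6] + 1)
})

test_that("genomic-transcript round trip and exon length conservation hold", {
  for (seed in 1:3) {
    sim <- simulate_editome(sim_config(n_genes = 4, seed = seed))
    for (gm in sim$genes) {
      tm <- transcript_map(gm, sim$genome)
      body <- tm$body[tm$body$region == "body", ]
      expect_equal(nrow(body), sum(gm$exons$end - gm$exons$start))
      expect_equal(max(body$tpos), tm$length)
      # bijection: each genomic position maps to exactly one tpos and back
      expect_false(any(duplicated(paste(body$contig, body$gpos))))
      expect_equal(body$tpos, seq_len(nrow(body)))
      # intron names regenerate from exon structure
      if (nrow(gm$introns)) {
        lens <- gm$exons$end - gm$exons$start
        expect_equal(gm$introns$name,
                     sprintf("%si%dg%d", gm$name,
                             cumsum(lens)[seq_len(nrow(gm$introns))],
                             gm$introns$group))
      }
    }
  }
})

test_that("a trans-spliced gene yields the same transcript as its cis twin", {
  cds <- paste(c("ATG", rep("TCA", 40), "TAA"), collapse = "")
  e1 <- 50L
  intr <- strrep("G", 200)
  seq1 <- paste0("AAAA", substr(cds, 1, e1), intr,
                 substr(cds, e1 + 1, nchar(cds)), "AAAA")
  cis <- gene_model("gX", "CDS",
                    exons = data.frame(contig = "c1",
                                       start = c(4, 4 + e1 + 200),
                                       end = c(4 + e1, 4 + 200 + nchar(cds)),
                                       strand = "+"),
                    introns = data.frame(group = 1L))
  gen1 <- genome(c(c1 = seq1))
  # same gene split over two contigs, second exon on the minus strand
  partA <- paste0("AAAA", substr(cds, 1, e1), strrep("G", 90))
  exon2 <- substr(cds, e1 + 1, nchar(cds))
  partB_plus <- paste0(strrep("G", 110), exon2, "AAAA")
  partB <- paste(rev(strsplit(chartr("ACGT", "TGCA", partB_plus), "")[[1]]),
                 collapse = "")
  gen2 <- genome(c(c1 = partA, c2 = partB))
  e2_start_minus <- nchar(partB) - (110 + nchar(exon2))
  trans <- gene_model("gX", "CDS",
                      exons = data.frame(contig = c("c1", "c2"),
                                         start = c(4, e2_start_minus),
                                         end = c(4 + e1, e2_start_minus + nchar(exon2)),
                                         strand = c("+", "-")),
                      introns = data.frame(group = 1L, cis = FALSE,
                                           len5 = 90, len3 = 110))
  expect_equal(transcript_sequence(cis, gen1), cds)
  expect_equal(transcript_sequence(trans, gen2), cds)
  expect_false(trans$introns$cis)
  # cumulative intron offsets continue from the 5' part into the 3' part
  tmt <- transcript_map(trans, gen2)
  expect_equal(sort(tmt$intron$offset), 1:200)
  expect_equal(unique(tmt$intron$intron), "gXi50g1")
})

test_that("locate applies feature precedence and codon arithmetic", {
  fx <- make_gene_fixture("atpB", c("ATG", rep("GGT", 460)), utr5 = 8L)
  w <- gpos_at(fx$gene, fx$genome, tpos = 1381)
  loc <- locate_position(w$contig, w$pos, list(fx$gene), fx$genome)
  expect_equal(loc$category, "CDS")
  expect_equal(loc$codon_index, 461)
  expect_equal(loc$codon_pos, 1)

  petB <- make_gene_fixture("petB", c("ATG", "GGT"), intron_after = 3L,
                            intron_len = 100L)
  wi <- gpos_at(petB$gene, petB$genome, intron_offset = 7)
  loci <- locate_position(wi$contig, wi$pos, list(petB$gene), petB$genome)
  expect_equal(loci$category, "intron")
  expect_equal(loci$intron, "petBi3g2")

  locn <- locate_position("ctg_petB", 1, list(petB$gene), petB$genome)
  expect_equal(locn$category, "intergenic")
})

test_that("overlapping exon segments within one gene are rejected", {
  expect_error(gene_model("bad", "CDS",
                          exons = data.frame(contig = "c1",
                                             start = c(0, 50), end = c(100, 150),
                                             strand = "+"),
                          introns = data.frame(group = 2L)),
               "overlapping")
})
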