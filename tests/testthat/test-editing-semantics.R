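code <- Biostrings::getGeneticCode("1")

# enumerate all subsets of a position vector (oracle helper)
combn_all <- function(v) {
  out <- list(integer(0))
  for (k in seq_along(v)) out <- c(out, utils::combn(v, k, simplify = FALSE))
  out
}

test_that("codon edits apply C->T / T->C and reject inconsistent edits", {
  expect_equal(apply_codon_edits("CCC", 2, "CtoU"), "CTC")
  expect_equal(apply_codon_edits("CCC", c(1, 2), "CtoU"), "TTC")
  expect_equal(apply_codon_edits("TAA", 1, "UtoC"), "CAA")
  expect_equal(apply_codon_edits("ACG", integer(0), character(0)), "ACG")
  expect_error(apply_codon_edits("AAA", 1, "CtoU"), "base is A")
  expect_error(apply_codon_edits("ACG", 2, "UtoC"), "base is C")
})

test_that("individual vs cumulative effects resolve multi-edit codons", {
  # CCA proline codon edited at positions 1 and 2: the first-position edit
  # alone restores serine, together with the second it gives leucine
  cls <- classify_codon_edits("CCA", c(1, 2), "CtoU", code)
  expect_equal(paste0(cls$ind_before[1], cls$ind_after[1]), "PS")
  expect_equal(paste0(cls$cum_before[1], cls$cum_after[1]), "PL")
  expect_equal(paste0(cls$ind_before[2], cls$ind_after[2]), "PL")
  expect_false(any(cls$silent))

  # third-position edit of a triple-edited CCC codon is silent in any context
  cls3 <- classify_codon_edits("CCC", c(1, 2, 3), "CtoU", code)
  expect_true(cls3$silent[3])
  expect_false(cls3$silent[1] || cls3$silent[2])
  expect_equal(paste0(cls3$ctx_before[3], cls3$ctx_after[3]), "FF")

  # ACG start codon repaired to ATG
  clsA <- classify_codon_edits("ACG", 2, "CtoU", code)
  expect_true(clsA$start_created)
  expect_equal(paste0(clsA$ind_before, clsA$ind_after), "TM")
})

test_that("brute-force enumeration over all edit subsets agrees", {
  set.seed(11)
  for (rep in 1:40) {
    codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    b <- strsplit(codon, "")[[1]]
    editable <- which(b %in% c("C", "T"))
    if (!length(editable)) next
    k <- sample(length(editable), 1)
    positions <- sort(editable[sample.int(length(editable), k)])
    types <- ifelse(b[positions] == "C", "CtoU", "UtoC")
    cls <- classify_codon_edits(codon, positions, types, code)
    # oracle: direct base substitution + translation, over all 2^k subsets
    subst <- function(pos_set) {
      bb <- b
      for (p in pos_set) bb[p] <- if (bb[p] == "C") "T" else "C"
      code[[paste(bb, collapse = "")]]
    }
    for (i in seq_along(positions)) {
      expect_equal(cls$ind_before[i], subst(integer(0)))
      expect_equal(cls$ind_after[i], subst(positions[i]))
      expect_equal(cls$cum_after[i], subst(positions))
      expect_equal(cls$ctx_before[i], subst(setdiff(positions, positions[i])))
      # silent = no amino-acid change in either the unedited or the fully
      # edited context, both recomputed here by direct translation
      expect_equal(cls$silent[i],
                   subst(integer(0)) == subst(positions[i]) &&
                     subst(setdiff(positions, positions[i])) == subst(positions))
    }
  }
})

test_that("the CCC proline codon spans exactly the four identities P, L, S, F", {
  subsets <- combn_all(1:3)
  ids <- vapply(subsets, function(s)
    code[[apply_codon_edits("CCC", s, rep("CtoU", length(s)))]], character(1))
  expect_setequal(unique(ids), c("P", "L", "S", "F"))
})

test_that("first-position U-to-C edits of stop codons give glutamine or arginine", {
  expect_equal(code[[apply_codon_edits("TAA", 1, "UtoC")]], "Q")
  expect_equal(code[[apply_codon_edits("TAG", 1, "UtoC")]], "Q")
  expect_equal(code[[apply_codon_edits("TGA", 1, "UtoC")]], "R")
  cls <- classify_codon_edits("TGA", 1, "UtoC", code)
  expect_true(cls$stop_removed)
})

test_that("annotation reproduces the worked-example labels verbatim", {
  wx <- worked_examples()
  sites <- annotate_edits(wx$calls, wx$genes, wx$genome)
  expect_equal(sites$label, wx$expected)
  # effect flags on the named cases
  expect_true(sites$stop_removed[sites$label == "rpoC2eC232*Q"])
  expect_true(sites$stop_created[sites$label == "rps2eU349R*"])
  expect_equal(sites$category[sites$label == "accDeU-1"], "5'UTR")
  expect_equal(sites$category[sites$label == "petBi6g2eU478"], "intron")
  expect_true(sites$silent[sites$label == "rpoBeU663PP_FF"])
})

test_that("single-edit codons have equal pairs and no pipe in the label", {
  fx <- make_gene_fixture("psbB", c("ATG", rep("GGT", 37), "TCA", "GGT"))
  call <- call_at(fx$gene, fx$genome, "CtoU", tpos = 116)
  site <- annotate_edits(call, list(psbB = fx$gene), fx$genome)
  expect_equal(site$ind_after, site$cum_after)
  expect_false(grepl("|", site$label, fixed = TRUE))
  expect_false(site$multi)
})

test_that("label parsing recovers components of published label styles", {
  p <- parse_edit_label("rpoBeU662PF|PL")
  expect_equal(p$gene, "rpoB")
  expect_equal(p$type, "CtoU")
  expect_equal(p$position, 662)
  expect_equal(paste0(p$cum_before, p$cum_after), "PF")
  expect_equal(paste0(p$ind_before, p$ind_after), "PL")

  p2 <- parse_edit_label("accDeU-1")
  expect_equal(p2$category, "5'UTR")
  expect_equal(p2$position, -1)

  p3 <- parse_edit_label("petBi6g2eU478")
  expect_equal(p3$category, "intron")
  expect_equal(p3$gene, "petB")
  expect_equal(p3$intron, "petBi6g2")

  p4 <- parse_edit_label("rpoC2eC232*Q")
  expect_equal(p4$type, "UtoC")
  expect_true(p4$stop_removed)

  bad <- parse_edit_label("notalabel")
  expect_false(bad$ok)
  expect_match(bad$error, "does not match")
})

test_that("parse and format are mutually inverse over fuzzed labels", {
  set.seed(99)
  labs <- random_labels(1000)
  parsed <- parse_edit_label(labs)
  expect_true(all(parsed$ok))
  expect_equal(format_parsed_label(parsed), labs)
})
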