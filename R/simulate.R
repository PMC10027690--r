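#' Configuration for the synthetic editome generator
#'
#' Describes a seeded toy organelle data set with the statistical structure
#' the pipeline assumes: genes whose genomic sequence needs RNA editing to
#' yield a clean reading frame (in-frame stops removed by U-to-C editing,
#' ACG starts converted to AUG by C-to-U editing), per-site editing
#' efficiencies spanning the observed 1-99% range, binomially sampled RNA
#' base counts over configurable coverage, and sequencing-error noise.
#'
#' Default mix parameters mirror a fern-type mitochondrial editome: about
#' two thirds of edits are C-to-U; roughly a quarter of the C-to-U codon
#' edits are silent; just under half of the U-to-C edits remove genomic stop
#' codons; DNA depth ~150x and deeper RNA coverage.
#'
#' @param n_genes Number of genes.
#' @param codons Range (min, max) of coding length in codons.
#' @param intron_prob Probability that a gene carries one intron.
#' @param group2_frac Fraction of introns that are group II (vs group I).
#' @param trans_frac Fraction of intron-bearing genes whose intron is
#'   trans-spliced (second exon on a separate contig).
#' @param utr5,utr3 Annotated UTR extents in nt.
#' @param edits_per_gene Range of planted coding edits per gene.
#' @param ctou_frac Fraction of edits of the C-to-U type.
#' @param efficiency Either a single percentage applied to every site or a
#'   (min, max) range sampled uniformly.
#' @param silent_frac Fraction of C-to-U codon edits that are silent.
#' @param stop_removal_frac Fraction of U-to-C edits that remove a genomic
#'   stop codon.
#' @param start_create_prob Probability that a gene's start is a genomic ACG
#'   repaired to AUG by C-to-U editing at transcript position 2.
#' @param intron_edit_prob,utr_edit_prob Probability of one additional
#'   intron-internal / 5'-UTR edit per eligible gene.
#' @param dna_coverage,rna_coverage Read depths for the simulated pileups.
#' @param error_rate Per-read sequencing error probability.
#' @param overdispersion Beta-binomial overdispersion rho in [0, 1); 0 gives
#'   plain binomial sampling of edited read counts.
#' @param seed Integer seed keying the generator's RNG stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6L, codons = c(60L, 150L), intron_prob = 0.5,
                       group2_frac = 0.85, trans_frac = 0.2,
                       utr5 = 30L, utr3 = 30L,
                       edits_per_gene = c(3L, 10L), ctou_frac = 0.67,
                       efficiency = c(1, 99), silent_frac = 0.25,
                       stop_removal_frac = 0.44, start_create_prob = 0.15,
                       intron_edit_prob = 0.5, utr_edit_prob = 0.3,
                       dna_coverage = 150L, rna_coverage = 500L,
                       error_rate = 0.001, overdispersion = 0,
                       seed = 1L) {
  probs <- c(intron_prob, group2_frac, trans_frac, ctou_frac, silent_frac,
             stop_removal_frac, start_create_prob, intron_edit_prob,
             utr_edit_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (dna_coverage < 1 || rna_coverage < 1) stopf("coverages must be >= 1")
  if (max(edits_per_gene) > min(codons) - 2)
    stopf("more planted edits (%d) than available codons (%d)",
          max(edits_per_gene), min(codons) - 2)
  structure(list(n_genes = as.integer(n_genes), codons = as.integer(codons),
                 intron_prob = intron_prob, group2_frac = group2_frac,
                 trans_frac = trans_frac, utr5 = as.integer(utr5),
                 utr3 = as.integer(utr3),
                 edits_per_gene = as.integer(edits_per_gene),
                 ctou_frac = ctou_frac, efficiency = efficiency,
                 silent_frac = silent_frac,
                 stop_removal_frac = stop_removal_frac,
                 start_create_prob = start_create_prob,
                 intron_edit_prob = intron_edit_prob,
                 utr_edit_prob = utr_edit_prob,
                 dna_coverage = as.integer(dna_coverage),
                 rna_coverage = as.integer(rna_coverage),
                 error_rate = error_rate, overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
NONSTOP <- setdiff(ALL_CODONS, STOPS)

# (codon, position) pools for planting edits, classified by the effect of
# the single base change; computed once per session.
edit_pools <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- genetic_code_for(1L)
    rows <- list()
    for (cdn in ALL_CODONS) for (p in 1:3) {
      b <- substr(cdn, p, p)
      if (b == "C") {
        ed <- cdn; substr(ed, p, p) <- "T"
        rows[[length(rows) + 1]] <- data.frame(
          codon = cdn, pos = p, type = "CtoU", edited = ed,
          before = code[[cdn]], after = code[[ed]])
      } else if (b == "T") {
        ed <- cdn; substr(ed, p, p) <- "C"
        rows[[length(rows) + 1]] <- data.frame(
          codon = cdn, pos = p, type = "UtoC", edited = ed,
          before = code[[cdn]], after = code[[ed]])
      }
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

pick_efficiency <- function(spec, n) {
  if (length(spec) == 1) rep(spec, n) else stats::runif(n, spec[1], spec[2])
}

#' Simulate a toy organelle genome with a planted editome
#'
#' Generates contig sequences, gene models and a truth table of planted
#' editing sites under a fixed seed. Coding sequences are random non-stop
#' codons; planted U-to-C stop removals are the only in-frame genomic stop
#' codons, planted start creations use a genomic ACG start, and each codon
#' carries at most one planted edit so every expected label is a plain
#' before/after pair. Genes land on either strand; a configurable fraction
#' of intron-bearing genes is split across two contigs and rejoined by a
#' trans-spliced intron.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the generator stream (defaults to `config$seed`).
#' @return A list of class `sim_editome` with `$genome`
#'   (`editome_genome`), `$genes` (named list of [gene_model()]),
#'   `$truth` (data.frame: `gene`, `contig`, `pos`, `strand`, `type`,
#'   `ref_fwd`, `edited_fwd`, `efficiency`, `category`, `label`) and
#'   `$config`.
#' @export
simulate_editome <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  pools <- edit_pools()
  pool_ctou_ns <- pools[pools$type == "CtoU" & pools$before != pools$after &
                          pools$after != "*" & pools$before != "*", ]
  pool_ctou_s <- pools[pools$type == "CtoU" & pools$before == pools$after &
                         pools$before != "*", ]
  pool_utoc_ns <- pools[pools$type == "UtoC" & pools$before != "*" &
                          pools$before != pools$after, ]

  spacer_len <- 150L
  contigs <- list(ctgA = character(0), ctgB = character(0))
  cursor <- c(ctgA = 0L, ctgB = 0L)
  genes <- list()
  truth <- list()
  spans <- list()  # transcribed genomic spans, for RNA coverage simulation

  append_seq <- function(ctg, s) {
    contigs[[ctg]] <<- c(contigs[[ctg]], s)
    start <- cursor[[ctg]]
    cursor[[ctg]] <<- cursor[[ctg]] + nchar(s)
    start
  }

  for (gi in seq_len(config$n_genes)) {
    gname <- sprintf("sgene%02d", gi)
    n_cod <- sample(config$codons[1]:config$codons[2], 1)
    L <- 3L * n_cod
    start_edit <- stats::runif(1) < config$start_create_prob
    cods <- c(if (start_edit) "ACG" else "ATG",
              sample(NONSTOP, n_cod - 2, replace = TRUE), "TAA")

    # plan coding edits: at most one per codon, never in start/stop codon
    m <- sample(config$edits_per_gene[1]:config$edits_per_gene[2], 1)
    cand <- 2:(n_cod - 1)
    idx <- sort(sample(cand, min(m, length(cand))))
    plan <- list()
    for (ci in idx) {
      ctou <- stats::runif(1) < config$ctou_frac
      if (!ctou && stats::runif(1) < config$stop_removal_frac) {
        stop_cdn <- sample(STOPS, 1)
        row <- pools[pools$codon == stop_cdn & pools$pos == 1 &
                       pools$type == "UtoC", ]
      } else if (!ctou) {
        row <- pool_utoc_ns[sample(nrow(pool_utoc_ns), 1), ]
      } else if (stats::runif(1) < config$silent_frac) {
        row <- pool_ctou_s[sample(nrow(pool_ctou_s), 1), ]
      } else {
        row <- pool_ctou_ns[sample(nrow(pool_ctou_ns), 1), ]
      }
      cods[ci] <- row$codon
      tpos <- 3L * (ci - 1L) + row$pos
      plan[[length(plan) + 1]] <- data.frame(
        tpos = tpos, type = row$type, before = row$before, after = row$after,
        category = "CDS")
    }
    if (start_edit)
      plan[[length(plan) + 1]] <- data.frame(
        tpos = 2L, type = "CtoU", before = "T", after = "M", category = "CDS")
    plan <- do.call(rbind, plan)

    cds <- paste(cods, collapse = "")
    has_intron <- stats::runif(1) < config$intron_prob && L > 80
    intron_len <- 0L; exon1_len <- L
    intron_seq <- ""; group <- NA_integer_; intron_name <- NA_character_
    intron_edit <- NULL
    is_trans <- FALSE
    if (has_intron) {
      exon1_len <- sample(30:(L - 30), 1)
      intron_len <- sample(150:500, 1)
      intron_seq <- rand_seq(intron_len)
      group <- if (stats::runif(1) < config$group2_frac) 2L else 1L
      intron_name <- sprintf("%si%dg%d", gname, exon1_len, group)
      is_trans <- stats::runif(1) < config$trans_frac
      if (stats::runif(1) < config$intron_edit_prob && !is_trans) {
        off <- sample(intron_len, 1)
        ity <- if (stats::runif(1) < config$ctou_frac) "CtoU" else "UtoC"
        substr(intron_seq, off, off) <- if (ity == "CtoU") "C" else "T"
        intron_edit <- data.frame(offset = off, type = ity)
      }
    }
    utr5_seq <- rand_seq(config$utr5)
    utr3_seq <- rand_seq(config$utr3)
    utr_edit <- NULL
    if (config$utr5 > 0 && stats::runif(1) < config$utr_edit_prob) {
      k <- sample(config$utr5, 1)
      uty <- if (stats::runif(1) < config$ctou_frac) "CtoU" else "UtoC"
      substr(utr5_seq, config$utr5 - k + 1L, config$utr5 - k + 1L) <-
        if (uty == "CtoU") "C" else "T"
      utr_edit <- data.frame(k = k, type = uty)
    }

    exon1_seq <- substr(cds, 1, exon1_len)
    exon2_seq <- if (has_intron) substr(cds, exon1_len + 1, L) else ""
    strand <- sample(c("+", "-"), 1)
    split_at <- NA_integer_

    # block = transcript-orientation sequence; bidx = 0-based index within it
    bidx_of_tpos <- function(t) {
      config$utr5 + (if (has_intron && t > exon1_len) intron_len else 0L) + t - 1L
    }
    bidx_of_utr5 <- function(k) config$utr5 - k
    bidx_of_intron <- function(off) config$utr5 + exon1_len + off - 1L

    place <- function(ctg, block, strand) {
      # returns (start, gpos function over 0-based block index)
      append_seq(ctg, rand_seq(spacer_len))
      st <- append_seq(ctg, if (strand == "-") revcomp(block) else block)
      B <- nchar(block)
      list(start = st,
           gpos = function(b) if (strand == "+") st + b else st + B - 1L - b,
           span = c(st, st + B))
    }

    if (!is_trans) {
      block <- paste0(utr5_seq, exon1_seq, intron_seq, exon2_seq, utr3_seq)
      pl <- place("ctgA", block, strand)
      spans[[length(spans) + 1]] <- data.frame(contig = "ctgA",
                                               start = pl$span[1], end = pl$span[2])
      e1_b0 <- config$utr5
      exons <- if (has_intron) {
        b_ranges <- rbind(c(e1_b0, e1_b0 + exon1_len),
                          c(e1_b0 + exon1_len + intron_len,
                            e1_b0 + exon1_len + intron_len + (L - exon1_len)))
        data.frame(contig = "ctgA",
                   start = vapply(seq_len(2), function(k)
                     min(pl$gpos(b_ranges[k, 1]), pl$gpos(b_ranges[k, 2] - 1L)), 0),
                   end = vapply(seq_len(2), function(k)
                     max(pl$gpos(b_ranges[k, 1]), pl$gpos(b_ranges[k, 2] - 1L)) + 1L, 0),
                   strand = strand)
      } else {
        data.frame(contig = "ctgA",
                   start = min(pl$gpos(e1_b0), pl$gpos(e1_b0 + L - 1L)),
                   end = max(pl$gpos(e1_b0), pl$gpos(e1_b0 + L - 1L)) + 1L,
                   strand = strand)
      }
      gpos_of <- function(b) pl$gpos(b)
      ctg_of <- function(b) "ctgA"
    } else {
      split_at <- sample(50:(intron_len - 50), 1)
      blockA <- paste0(utr5_seq, exon1_seq, substr(intron_seq, 1, split_at))
      blockB <- paste0(substr(intron_seq, split_at + 1, intron_len),
                       exon2_seq, utr3_seq)
      strandB <- sample(c("+", "-"), 1)
      plA <- place("ctgA", blockA, strand)
      plB <- place("ctgB", blockB, strandB)
      spans[[length(spans) + 1]] <- data.frame(contig = "ctgA",
                                               start = plA$span[1], end = plA$span[2])
      spans[[length(spans) + 1]] <- data.frame(contig = "ctgB",
                                               start = plB$span[1], end = plB$span[2])
      e1_b0 <- config$utr5
      lenB_intron <- intron_len - split_at
      exons <- data.frame(
        contig = c("ctgA", "ctgB"),
        start = c(min(plA$gpos(e1_b0), plA$gpos(e1_b0 + exon1_len - 1L)),
                  min(plB$gpos(lenB_intron), plB$gpos(lenB_intron + (L - exon1_len) - 1L))),
        end = c(max(plA$gpos(e1_b0), plA$gpos(e1_b0 + exon1_len - 1L)) + 1L,
                max(plB$gpos(lenB_intron), plB$gpos(lenB_intron + (L - exon1_len) - 1L)) + 1L),
        strand = c(strand, strandB))
      gpos_of <- function(b) {
        if (b < nchar(blockA)) plA$gpos(b) else plB$gpos(b - nchar(blockA))
      }
      ctg_of <- function(b) if (b < nchar(blockA)) "ctgA" else "ctgB"
    }

    introns <- if (has_intron) data.frame(
      group = group, cis = !is_trans,
      len5 = if (is_trans) split_at else NA_real_,
      len3 = if (is_trans) intron_len - split_at else NA_real_) else NULL
    gm <- gene_model(gname, kind = "CDS", exons = exons, introns = introns,
                     utr5 = config$utr5, utr3 = config$utr3)
    genes[[gname]] <- gm

    # truth records; the per-record strand is filled in afterwards from the
    # gene model (the contig a position falls on determines its strand)
    add_truth <- function(bidx, type, category, label, eff) {
      ctg <- if (is_trans) ctg_of(bidx) else "ctgA"
      truth[[length(truth) + 1]] <<- data.frame(
        gene = gname, contig = ctg, pos = gpos_of(bidx), strand = NA_character_,
        type = type, efficiency = eff, category = category, label = label)
    }

    effs <- pick_efficiency(config$efficiency,
                            nrow(plan) + (!is.null(intron_edit)) +
                              (!is.null(utr_edit)))
    ei <- 0L
    for (r in seq_len(nrow(plan))) {
      ei <- ei + 1L
      lab <- paste0(gname, "e", edit_letter(plan$type[r]), plan$tpos[r],
                    plan$before[r], plan$after[r])
      add_truth(bidx_of_tpos(plan$tpos[r]), plan$type[r], "CDS", lab, effs[ei])
    }
    if (!is.null(intron_edit)) {
      ei <- ei + 1L
      lab <- paste0(intron_name, "e", edit_letter(intron_edit$type),
                    intron_edit$offset)
      add_truth(bidx_of_intron(intron_edit$offset), intron_edit$type,
                "intron", lab, effs[ei])
    }
    if (!is.null(utr_edit)) {
      ei <- ei + 1L
      lab <- paste0(gname, "e", edit_letter(utr_edit$type), "-", utr_edit$k)
      add_truth(bidx_of_utr5(utr_edit$k), utr_edit$type, "5'UTR", lab, effs[ei])
    }
  }

  seqs <- vapply(contigs, paste, character(1), collapse = "")
  seqs <- seqs[nchar(seqs) > 0]
  gen <- genome(seqs)
  truth <- do.call(rbind, truth)
  # forward-strand ref/edited bases for pileup simulation
  truth$strand <- vapply(seq_len(nrow(truth)), function(i) {
    gm <- genes[[truth$gene[i]]]
    ex <- gm$exons[gm$exons$contig == truth$contig[i], , drop = FALSE]
    ex$strand[1]
  }, character(1))
  tx_ref <- ifelse(truth$type == "CtoU", "C", "T")
  tx_ed <- ifelse(truth$type == "CtoU", "T", "C")
  truth$ref_fwd <- ifelse(truth$strand == "+", tx_ref, comp_base(tx_ref))
  truth$edited_fwd <- ifelse(truth$strand == "+", tx_ed, comp_base(tx_ed))
  rownames(truth) <- NULL
  structure(list(genome = gen, genes = genes, truth = truth,
                 spans = do.call(rbind, spans), config = config),
            class = "sim_editome")
}

#' Simulate DNA and RNA pileups from a planted editome
#'
#' DNA pileups cover every contig position at the configured depth with
#' sequencing error distributed over the three non-reference bases. RNA
#' pileups cover the transcribed spans; at planted editing sites the edited
#' base count is drawn binomially (optionally beta-binomially) at the site's
#' true efficiency, and all other covered positions carry error-only noise,
#' so with a zero error rate the RNA pileup matches the DNA base at every
#' non-edited position.
#'
#' @param sim A `sim_editome` from [simulate_editome()].
#' @param seed RNG seed (defaults to the simulation's seed plus one so the
#'   genome and read layers use distinct deterministic streams).
#' @return A list with `$dna` and `$rna` pileup data.frames
#'   (`contig`, `pos`, `A`, `C`, `G`, `T`).
#' @export
simulate_pileups <- function(sim, seed = sim$config$seed + 1L) {
  set.seed(seed)
  cfg <- sim$config
  base_counts <- function(seq_chars, cov, err) {
    n <- length(seq_chars)
    counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
    n_err <- stats::rbinom(n, cov, err)
    e1 <- stats::rbinom(n, n_err, 1 / 3)
    e2 <- stats::rbinom(n, n_err - e1, 1 / 2)
    e3 <- n_err - e1 - e2
    ref_i <- match(seq_chars, BASES)
    for (b in 1:4) {
      others <- setdiff(1:4, b)
      sel <- which(ref_i == b)
      counts[sel, b] <- cov - n_err[sel]
      counts[sel, others[1]] <- counts[sel, others[1]] + e1[sel]
      counts[sel, others[2]] <- counts[sel, others[2]] + e2[sel]
      counts[sel, others[3]] <- counts[sel, others[3]] + e3[sel]
    }
    counts
  }
  dna <- list(); rna <- list()
  for (ctg in names(sim$genome$seq)) {
    chars <- strsplit(sim$genome$seq[[ctg]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    dmat <- base_counts(chars, cfg$dna_coverage, cfg$error_rate)
    dna[[ctg]] <- data.frame(contig = ctg, pos = 0:(n - 1), dmat)
    sp <- sim$spans[sim$spans$contig == ctg, , drop = FALSE]
    if (!nrow(sp)) next
    covered <- sort(unique(unlist(lapply(seq_len(nrow(sp)), function(k)
      seq(sp$start[k], sp$end[k] - 1L)))))
    rmat <- base_counts(chars[covered + 1L], cfg$rna_coverage, cfg$error_rate)
    rdf <- data.frame(contig = ctg, pos = covered, rmat)
    tr <- sim$truth[sim$truth$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      j <- match(tr$pos[i], rdf$pos)
      if (is.na(j)) next
      N <- cfg$rna_coverage
      p <- tr$efficiency[i] / 100
      if (cfg$overdispersion > 0) {
        rho <- cfg$overdispersion
        ab <- (1 - rho) / rho
        p <- stats::rbeta(1, p * ab, (1 - p) * ab)
      }
      edited_n <- stats::rbinom(1, N, p)
      err_e <- stats::rbinom(1, edited_n, cfg$error_rate)
      err_r <- stats::rbinom(1, N - edited_n, cfg$error_rate)
      row <- stats::setNames(rep(0L, 4), BASES)
      row[tr$edited_fwd[i]] <- edited_n - err_e
      row[tr$ref_fwd[i]] <- N - edited_n - err_r
      others <- setdiff(BASES, c(tr$edited_fwd[i], tr$ref_fwd[i]))
      spill <- err_e + err_r
      s1 <- stats::rbinom(1, spill, 0.5)
      row[others[1]] <- s1; row[others[2]] <- spill - s1
      rdf[j, BASES] <- as.list(row)
    }
    rna[[ctg]] <- rdf
  }
  dna <- do.call(rbind, dna); rna <- do.call(rbind, rna)
  rownames(dna) <- rownames(rna) <- NULL
  list(dna = dna, rna = rna)
}

#' Write a truth table
#' @param truth Truth data.frame from [simulate_editome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
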