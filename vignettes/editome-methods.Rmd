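---
title: "Methods: calling, labeling and summarizing organelle RNA editomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, labeling and summarizing organelle RNA editomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The problem

Plant chloroplast and mitochondrial transcripts are post-transcriptionally
edited: cytidines are deaminated to uridine (C-to-U, written `eU`), and in
many lycophytes, ferns and hornworts the reverse amination (U-to-C, `eC`)
occurs as well. Editing restores conserved codons, creates AUG start codons
from genomic ACG, and — in the U-to-C direction — removes genomic in-frame
stop codons, so a genomic reading frame full of stops may nonetheless encode
a functional protein. Characterizing an organelle "editome" therefore means
(i) detecting RNA–DNA differences site by site, (ii) quantifying what
fraction of transcripts is edited at each site, and (iii) interpreting each
edit in its codon and gene-structure context. This package implements that
workflow downstream of read mapping: its inputs are per-position base-count
tables (pileups) for a DNA and an RNA sample over the same reference, plus
the genome and its gene annotation.

## Detection model

For every position present in both pileups the DNA consensus base is taken
as the reference. A site is reported when all of the following hold:

1. **DNA homogeneity** — the consensus base carries at least 95% of DNA
   reads, at a minimum of 10 DNA reads. This gate replaces a statistical
   RNA–DNA difference test: its purpose is to exclude positions where the
   genomic base itself is ambiguous (collapsed repeats, paralogous copies),
   which are the dominant source of artifactual RNA–DNA differences in
   recombining mitogenomes.
2. **RNA coverage** — at least `min_rna_reads` (default 30) RNA reads carry
   either the reference or the edited base.
3. **Efficiency** — the editing efficiency reaches
   `min_frequency_percent`: 1% in chloroplast mode, 5% in mitochondrial
   mode. The two defaults reflect the different read depths typically
   achieved for the two organelles; both are plain hard thresholds, so no
   multiple-testing correction is involved.

Efficiency is estimated as

$$\mathrm{eff} = 100 \cdot \frac{n_\mathrm{edited}}{n_\mathrm{edited} + n_\mathrm{ref}}$$

and reported to three decimal places. Reads carrying neither the reference
nor the edited base are excluded from the denominator; they are sequencing
errors, and including them would bias all efficiencies downward by the error
rate. Thresholds are compared on the unrounded value, so a site at exactly
30 reads or exactly 1.000% passes and one at 29 reads or 0.999% does not.

Only four (forward reference base, strand) combinations can represent
editing on the transcribed strand: C/+ and G/− are C-to-U candidates, T/+
and A/− are U-to-C candidates. Inside annotated features the feature's
strand decides which combination applies; an unannotated position admits
exactly one orientation per reference base and is flagged intergenic.

## Coordinates and gene models

Internally all coordinates are 0-based half-open; everything user-facing is
1-based. Transcript positions count from the first nucleotide of the mature
coding or structural sequence; 5'-UTR positions are negative with −1
immediately upstream of position 1 and no position 0. Because no published
worked example fixes a 3'-UTR convention, we continue the positive
transcript numbering past the stop codon and flag the category — this keeps
every position of a transcript uniquely addressable by a single integer.

Genes may be split by introns, named `<gene>i<preceding exonic nt>g<group>`
(group I or II). Exon segments of one gene may lie on different contigs
and/or strands; such trans-spliced genes produce the same transcript
coordinate system as their cis-arranged twins (a property the test suite
checks explicitly). Interior positions of an intron are addressed by a
1-based offset; for a trans-spliced intron whose two genomic halves are
annotated with their extents, offsets continue cumulatively from the 5'
half into the 3' half — again chosen so a single integer addresses every
intron position, in the absence of a published within-part convention.

Where features overlap, location calls use the precedence
CDS > intron > UTR > rRNA/tRNA > intergenic, so that a coding consequence is
never masked by an overlapping non-coding annotation; all overlapping
contexts remain available to the caller. Translation uses the standard
genetic code (NCBI table 1) by default, which covers plant organelle coding
sequences; the table is configurable per gene.

## Codon effects and the label grammar

Labels follow the `<locus>e<U|C><position><effect>` convention, e.g.
`psbBeU116SL` (position 116, serine-to-leucine), `rpoC2eC232*Q` (a U-to-C
edit removing a stop), `accDeU-1` (5'-UTR), `petBi6g2eU478` (intron
offset 478).

Codons carrying several edits need more care, because the amino-acid
meaning of one edit depends on whether its neighbors are edited on the same
transcript molecule. For each member edit of a multi-edit codon we compute:

* the **individual pair** — reference codon vs. the codon with this edit
  alone;
* the **cumulative pair** — reference codon vs. the fully edited codon
  (all member edits applied).

Non-silent members are labeled `<cumulative>|<individual>`; the pipe is
emitted for *every* non-silent member of a multi-edit codon, even when the
two pairs coincide, so that the reader can see at a glance that the codon
carries other edits. A member that changes the amino acid neither in the
unedited nor in the fully edited context is silent and instead labeled
`<unedited pair>_<fully edited pair>` (e.g. `PP_FF` for a third-position
edit of CCC, silent for all four reachable codon identities P, L, S and F).
Intermediate edit combinations are not represented in the label.
Single-edit codons always use the plain two-letter pair, silent or not.

The cumulative context applies **all** called edits of the codon regardless
of their efficiencies: even a 1–2% minor edit defines a real transcript
subpopulation, and dropping low-frequency members would make labels depend
on the detection threshold. The grammar is fully invertible; `parse_edit_label()`
and `format_parsed_label()` round-trip every well-formed label, which is how
published edit tables are re-ingested and re-summarized without access to
the original pileups.

Effect flags are derived from the pairs: `stop_removed` (before `*`, after
not), `stop_created` (after `*`), `start_created` (a codon-1 non-ATG codon
whose fully edited form is ATG), `silent`, `codon_change`.

## Summary statistics

`summarize_editome()` partitions edits by type and location (each edit
counted exactly once), tallies effect flags per type, and averages
efficiencies per category × type cell. Means are unweighted averages of
per-site percentages — a deliberately simple statistic, unweighted by
coverage, matching how editome surveys report group averages.
`find_nesi()` flags silent coding edits lying within a window (default 3
transcript nucleotides, i.e. the same or an adjacent codon boundary region)
of a non-silent edit of the same gene; the window has no published numeric
definition, so it is an explicit parameter.

## Repeat junctions and arrangement stoichiometry

Recombining plant mitogenomes carry repeats whose copies each have distinct
upstream/downstream single-copy flanks. `enumerate_flank_pairings()` lists
all $n^2$ flank combinations for $n$ copies, distinguishing the $n$
parental continuities from recombinant ones; inverted copies swap flank
roles. `coverage_additivity()` checks the stoichiometric expectation that a
shared repeat's read depth approximates the sum of its flanking
arrangements' depths (e.g. 150× + 350× ≈ 500×) as a plain ratio test —
the published reasoning is about approximate sums, not a calibrated depth
model, so a tolerance band (default ±15%) is honest about the precision
actually used. `enumerate_circles()` enumerates simple cycles of the
contig/breakpoint graph, deduplicated under rotation and reflection and
capped (default 1000) because breakpoint graphs explode combinatorially.

## The synthetic-data generator

`simulate_editome()` builds seeded toy data sets with the features the
pipeline must handle: genes on both strands, cis- and trans-spliced introns
of both groups, 5'/3' UTRs, genomic ACG starts repaired by editing, genomic
in-frame stops (only at planted U-to-C stop-removal sites), silent edits,
and intron/UTR edits. Default mix parameters emulate a fern-type
mitochondrial editome: two thirds C-to-U, about a quarter of C-to-U codon
edits silent, just under half of U-to-C edits removing stops, efficiencies
uniform over 1–99%, DNA depth 150×, RNA depth 500×, error rate 0.1%.
`simulate_pileups()` draws edited read counts binomially at each site's
true efficiency (optionally beta-binomially via `overdispersion`) and
spreads sequencing errors uniformly over the other bases at constant depth.

The generator plants at most one edit per codon; multi-edit codon semantics
are exercised by constructed codon fixtures instead, where expected labels
can be stated by hand. What passing the simulation-based tests shows is that
coordinate mapping, calling, classification and labeling compose correctly
under known truth; it does not show robustness to features real data add —
variable and correlated coverage, mapping artifacts at splice junctions and
repeats, strand-biased errors, or cross-contamination between organelles.
The DNA homogeneity gate addresses the repeat problem only at positions
where the collapsed copies actually disagree.

## Numerical choices and problem sizes

* Efficiencies are stored and compared unrounded; only reporting rounds to
  3 decimals.
* DNA consensus ties resolve to the first base in A, C, G, T order; a tie
  cannot pass the 0.95 homogeneity gate, so the choice is inert.
* Degenerate inputs: empty pileups and empty edit tables yield valid empty
  outputs and all-zero summaries; an efficiency with zero total reads is an
  error, not NaN.
* Tests and the acceptance script use 4–10 genes of 40–200 codons and 200
  replicates of a one-gene data set at 500× RNA coverage; these sizes give
  binomial standard errors well below the tested tolerances (at 500× and
  20% efficiency, one s.e. ≈ 1.8 percentage points) while the full suite
  stays fast.

## Known limitations

* The caller works from pileups; alignment-level artifacts (indels, clipped
  reads, splice-junction mapping) must be handled upstream.
* Editing prediction classes (strongly/moderately/weakly expected) are
  consumed from input columns when present, never computed.
* The label grammar cannot distinguish 3'-UTR from rRNA/tRNA positions
  without the annotation; parsed labels of that shape are reported as a
  single non-CDS category.
* Circular-contig support covers coordinate wrap-around of features, not
  origin-spanning pileup bookkeeping, which is the pileup producer's job.
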