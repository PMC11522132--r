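---
title: "Predicting transcription outcomes of the En2 cryptic splice site"
author: "en2splice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transcription outcomes of the En2 cryptic splice site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(en2splice)
```

## The problem

Knockout-first (tm1a) alleles produced by the IKMC carry a large
lacZ/neo disruption cassette in the intron upstream of a "critical" exon.
To splice the lacZ reporter into the host transcript, the cassette begins
with the 158 bp splice-acceptor sequence of the mouse *En2* gene. That
sequence harbours an unintended splice-donor motif ("aggt") 115 bases in:
when the spliceosome uses this cryptic donor, the first 115 bp of the
acceptor are retained in the mature mRNA instead of (or in addition to)
disrupting it. Depending on where the insert lands relative to the
critical exon and on the exon's reading-frame phases, the outcome ranges
from a frameshift through a premature stop codon inside the insert to a
clean readthrough that swaps 38 codons of *En2*-derived sequence into the
protein. Researchers using these alleles — and the tm1b (lacZ-tagged
deletion) and tm1e (targeted non-conditional) alleles derived from the
same design — need to know which of these outcomes to expect before
interpreting a "knockout" phenotype.

`en2splice` implements the frame arithmetic for this prediction, applies
it in bulk to allele-design tables with Ensembl/BioMart-style exon phases,
aggregates IMPC-style phenotype and lacZ-expression data by predicted
outcome, and generates seeded synthetic datasets with known ground truth
so the entire pipeline is testable offline.

## The frame model

Exon phases follow the Ensembl convention: the *start phase* of an exon is
the number of bases of the codon split across the upstream junction that
were contributed by the *previous* exon, so the end phase of one exon
equals the start phase of the next, and a fully coding exon of length
$L$ entered at phase $p$ ends in phase $(p + L) \bmod 3$. Phase $-1$
marks a boundary lying in untranslated sequence, where frame arithmetic
does not apply.

Three facts about the retained insert drive every prediction:

1. **Its length is 115, and $115 \bmod 3 = 1$.** Inserted before an
   intact critical exon (the usual tm1a behaviour), it cannot preserve the
   downstream frame from phase-0 or phase-1 junctions: the result is a
   frameshift.
2. **Read from a phase-2 junction, the insert contains an in-frame TAA.**
   One base of the insert completes the upstream codon, and the twelfth
   codon of the resulting frame is a stop: translation yields
   `(g)SQVPKTKEEEP*` and terminates inside the insert. The TAA occupies
   insert bases 35–37 (1-based, inclusive; i.e. it *ends* at base 37).
   The phase-0 and phase-1 frames contain no stop codon anywhere in the
   115 bases, which the test suite verifies against an independently coded
   codon scan.
3. **Replacing the critical exon, the insert ends in phase
   $(p + 115) \bmod 3$.** Readthrough therefore occurs exactly when the
   replaced exon's end phase matches that value; any mismatch shifts the
   downstream frame.

These combine into the classification over the nine non-negative
(start, end) phase pairs:

```{r}
phaseCombinationTable()
```

Two edge rules complete the classifier (`classifyDesign()`):

* An exon starting in phase 2 but ending in a negative phase still reads
  the insert into the internal TAA, so it joins the `STOP_IN_INSERT`
  category rather than `OTHER`.
* Every other pair touching a negative phase is `OTHER`: the affected
  boundary lies in non-coding sequence and the coding-frame argument does
  not apply.

A further boundary case is handled by `boundaryStopCheck()`: if the exon
upstream of the insertion ends in phase 2 with the bases `ta`, the first
`g` of the insert completes a TAG stop at the junction itself. With this
insert (which begins `gt...`) that is the only upstream suffix able to do
so.

### Insertion before the critical exon

For tm1a-style insertion *before* the critical exon the package
distinguishes phase-2 junctions (`STOP_IN_INSERT`, via the internal TAA)
from phase-0/1 junctions (`FRAMESHIFT`). Both are loss-of-frame outcomes,
and some users prefer the single blanket label "frameshift" for all
before-exon insertions; `collapseStop = TRUE` (the CLI's
`--collapse-tm1a-stop`) folds the phase-2 case into `FRAMESHIFT` for that
reading. The finer default was chosen because it is the truthful
consequence of the same frame logic that produces the nine-pair table.

### Insertion mode and allele class

By default, knockout-first (tm1a-like) and targeted non-conditional
(tm1e-like) designs are classified in BEFORE mode and lacZ-tagged
deletions (tm1b-like) in REPLACES mode. The mapping is a default, not a
law: knockout-first alleles have occasionally been observed with the
insert in place of the critical exon, so `predictAll(bothModes = TRUE)`
emits both predictions per design. Conditional (tm1c-like) alleles rescue
normal splicing and are skipped with an explicit tally.

### Multi-exon critical blocks

When a design deletes several consecutive exons the phase pair is taken
as (start phase of the first exon, end phase of the last): the insert
replaces the whole block and the interior boundaries are spliced out of
existence. Non-consecutive blocks are a hard error; exon ids that cannot
be found make the design drop out into a "no phase information" tally
rather than vanish silently. When a gene model offers several transcripts
containing the critical exons, the design's named transcript wins;
otherwise the lexicographically smallest qualifying transcript id is used
with a warning, so runs are deterministic.

## Phenotype aggregation

`summarizeCategories()` reproduces the structure of a per-category
phenotype audit: for each outcome category and allele group
(tm1a/tm1e versus tm1b) it reports predicted genes, genes with no
phenotype rows for that group ("untested"), tested lines, lines with no
significant MP (Mammalian Phenotype) term, lines with a lethality
phenotype, and the mean number of MP terms per tested line (the
denominator is all tested lines, including those with none). Genes whose
designs land in more than one category are excluded from every row,
because phenotype data cannot then be attributed to a single design.
Zero tested lines yield `NaN`, not 0, for the per-line mean.

Decisions a maintainer should know about:

* **Lethality** is detected by a case-insensitive substring match for
  "lethal" on term names, which captures the preweaning/embryonic/
  postnatal lethality families without bundling the MP ontology. An
  MP-id allowlist can be supplied for stricter, ontology-driven matching.
* **Lines** are whatever the line/colony-id column identifies; the
  package takes that identity at face value and does not attempt to merge
  colonies or zygosities.
* **Significance is input, not computed.** MP terms in the input are
  assumed to be pre-thresholded significant calls (as in IMPC exports);
  the package performs no statistical re-testing.
* **lacZ silence** (`laczSilentGenes()`) requires at least 27 distinct
  assayed tissues, all negative; genes with thinner coverage are never
  called silent. Tissue names are trimmed and case-folded, and duplicate
  gene × tissue rows collapse by logical OR.

## The synthetic-data generator

`simulationConfig()` + `generateGeneModels()` / `generateDesigns()` /
`generatePhenotypeCohort()` emulate the statistical structure the
pipeline consumes:

* **Gene models** are single-transcript exon chains whose phases compose
  correctly (`end == (start + length) mod 3` for coding exons, chained
  boundaries equal, UTR-adjacent boundaries −1 with probability
  `utr_flank_probability`). Each gene carries a designated internal
  critical block whose (start, end) pair is drawn from
  `phase_pair_weights`, or cycled deterministically through the nine
  pairs when `balanced_phase_pairs = TRUE` — the latter gives *exact*
  category proportions, which is what a calibration run wants. Critical
  exon lengths avoid multiples of 3 whenever the assigned pair permits
  (equal start and end phases force a multiple of 3).
* **Cohorts** draw, per tested line, zero MP terms with probability
  `no_phenotype_fraction` and otherwise a zero-truncated Poisson count
  whose underlying rate is solved numerically so the *marginal* mean per
  tested line equals `mp_terms_per_line_mean`; a lethality-named term is
  included so the marginal probability of a lethal line equals
  `lethal_fraction` (hence the constraint
  `lethal_fraction <= 1 - no_phenotype_fraction`). Term names come from a
  small built-in vocabulary with both lethal and non-lethal entries.
* **Defaults are the study conditions**: ~70% of genes untested, 15% of
  tested lines with no phenotype, 35% with a lethality phenotype, 4.5 MP
  terms per tested line, lacZ assayed in 30 tissues with a silent-gene
  probability of 36/2909 ≈ 1.24%, and a tm1a-heavy allele mix — the
  broad characteristics of the IMPC knockout-first resource.

Everything is deterministic given `seed` (R's default Mersenne-Twister;
the three generators use `seed`, `seed + 1`, `seed + 2` so stages are
reproducible independently).

What the generator does **not** emulate: genomic coordinates, sequence
content beyond phases and lengths, the MP ontology graph, correlations
between predicted category and phenotype burden (categories and
phenotypes are generated independently), or multi-design genes. Passing
round-trip tests therefore demonstrates that the pipeline classifies,
joins and counts correctly — not that real knockout-first data behave
like the simulation.

## Numerical and design choices

* Sequences are canonicalised to lowercase internally; inputs are
  case-insensitive. Non-ACGT bases are rejected before translation.
* The stop-codon set is the standard nuclear code {TAA, TAG, TGA}.
* Insert coordinates are 1-based inclusive on the 115 bp insert; the
  phase-2 stop is reported as bases 35–37 (the codon *ends* at 37).
* Problem sizes used by the verification scripts — 9,000 designs for the
  balanced category split, 1,000 tested lines for parameter recovery,
  2,909 genes for the lacZ screen — are large enough for exact or
  3-standard-error checks while keeping a full run in seconds.
* Parsers reject rows, never whole files, where a row-level fix is
  meaningful (bad phases), and fail hard where silent repair would
  corrupt results (missing columns, duplicate transcript ranks,
  non-consecutive critical exons).

## Limitations

* The cryptic donor is taken as given; the package does not predict
  splice-site usage or strength, nor the tissue-specific variability with
  which the insertion is actually observed.
* "Leaky" correctly spliced full-length transcription — a separate escape
  route from cassette disruption — is out of scope.
* Readthrough predicts an in-frame protein containing 38 foreign
  residues; whether that protein is functional, hypomorphic or null is a
  biological question the classifier cannot answer.
* The tm1a/tm1b mode mapping is a default; where RT-PCR evidence exists
  for a specific allele it should override the prediction.
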