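---
title: "Evidence-based annotation quality control with aedqc"
author: "aedqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based annotation quality control with aedqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(aedqc))
suppressPackageStartupMessages(library(GenomicRanges))
```

## The problem

Genome annotation is never finished. Gene models inherited from early
releases drift out of step with the transcript and protein alignments
that accumulate afterwards; some models were never supported by any
evidence in the first place; and some well-supported loci carry no model
at all. Curators need a way to score every model against the evidence,
rank the doubtful ones for review, and—when several competing annotation
sets exist—pick the best-supported model at each locus.

`aedqc` implements this workflow on plain GFF3: gene/mRNA/exon
hierarchies for annotations, match/match_part hierarchies for aligned
evidence (ESTs, protein homology, mRNA-seq assemblies), BLAST tabular
files for orthology, and TSV attribute tables for enrichment reports.

## Annotation Edit Distance

The classical way to evaluate a gene prediction $i$ against a trusted
reference $j$ is base-pair sensitivity and specificity:

$$SN = \frac{|i \cap j|}{|j|}, \qquad SP = \frac{|i \cap j|}{|i|},$$

with accuracy their average. During quality control there is no trusted
reference, so the evidence itself stands in for $j$: all evidence
alignments and gene models are clustered into loci by transitive genomic
overlap (single linkage), and each transcript is compared against the
union of evidence positions in its own locus. Because the comparator is
not a curated reference, the average of $SN$ and $SP$ is called the
*congruency* $C = (SN + SP)/2$, and the score reported per transcript is
the distance

$$AED = 1 - C,$$

which is 0 when the exon footprint equals the evidence footprint and 1
when the model overlaps no evidence at all. Distances near 1 mark models
that are either recent inventions of a predictor (likely false
positives) or genuinely novel genes; both deserve a curator's eye first,
which is exactly the order `prioritizeForReview()` produces.

```{r worked}
exons <- GRanges("chr1", IRanges::IRanges(101, 200), "+")
est <- EvidenceSet(GRangesList(e1 = GRanges("chr1", IRanges::IRanges(151, 270), "+")),
                   "EST")
as.data.frame(computeAED(exons, est)[, c("sn", "sp", "congruency", "aed")])
```

A 100 bp exon against a 120 bp alignment sharing 50 bases gives
$SN = 50/120 \approx 0.4167$, $SP = 50/100 = 0.5$, AED $\approx 0.5417$.

## Conventions and tunable parameters

**Coordinates.** GFF3 throughout: 1-based, fully closed. Interval
normalization merges overlapping intervals but deliberately keeps
book-ended ones (`[1,10]`,`[11,20]`) separate: coverage counts are
unaffected and exon boundaries survive for the exon-level metrics.

**Clustering** (`clusterSingleLinkage()`, used by `computeAEDSet()` and
`buildLoci()`). Linkage requires at least `minOverlap = 1` shared base;
there is no minimum-overlap fraction, which is the simplest defensible
reading of an overlap cluster, and the threshold is exposed for callers
who want a stricter rule. Strand policy defaults to `"aware"`: equal
strands link, and unstranded features link to either strand, because
protein alignments are routinely reported unstranded. `"strict"` and
`"ignore"` modes are provided; none of the three is canonical, so the
choice is a documented parameter rather than a constant.

**The evidence denominator |j|.** "Total evidence bases in the cluster"
could mean the union of evidence positions or the sum over alignments.
The default is the union: under the sum, ten identical ESTs confirming a
perfect model would drive $SN$ toward zero, contradicting the boundary
semantics that complete agreement scores 0. The sum variant remains
available (`jMode = "sum"`) for comparison.

**Evidence classes.** By default all classes are pooled into one union
per locus (`classMode = "pooled"`); `"per-class"` scores each class
separately and keeps the best. When two classes jointly tile a model
(EST covering one end, protein the other), pooling can only help, and on
such jointly-covering inputs pooled AED is never worse than the best
single class. That dominance is *not* a theorem for arbitrary inputs: a
long protein alignment overhanging the locus can enlarge the pooled
union and worsen $SN$ relative to an EST-only comparison, which is why
both modes are exposed.

**Exons versus CDS.** AED is computed on exon coordinates by default,
since EST and mRNA-seq evidence covers untranslated regions;
`useCDS = TRUE` restricts scoring to coding coordinates for transcripts
that have a CDS. Protein alignment coordinates are consumed exactly as
given in the GFF3 (nucleotide genome coordinates, no codon scaling).

**Gene-level aggregation.** A gene's AED is the minimum over its
isoforms: a gene is as well supported as its best transcript.

## Consensus selection and re-annotation bookkeeping

`reannotate()` takes one or more annotation sets plus the evidence,
clusters everything into loci, and keeps per locus the candidate with
minimal AED ("most consistent with the evidence"). Ties fall back to the
larger exon-base count, then to source-set priority in the order the
sets were supplied, then to lexicographic transcript id—three
deterministic, documented steps rather than an arbitrary first-seen
winner.

Per-locus statuses: `kept_unchanged` (a reference candidate won),
`replaced` (a competing candidate displaced the reference, or the locus
has no reference candidate), `unsupported` (the winner's AED still meets
the review threshold, default 1.0; 0.95 is a useful setting when a
dataset's AED distribution spikes just below 1), and `evidence_only`
(evidence with no candidate model; a model is synthesized from the
merged evidence footprint, with book-ended segments kept as separate
exons).

The summary counts reference *gene models*: each is either unchanged or
altered, so `n_altered + n_unchanged = n_input_reference` holds on every
run by construction, and the identity is asserted in the tests. One
deliberate narrowing: this package selects among supplied models and
synthesizes evidence-only models, but does not revise exon boundaries
with ab initio predictors—"altered" therefore always means displaced by
a better-scoring supplied or synthesized model. Workflows that re-run
gene predictors can feed those predictions in as one more annotation
set, which is also how a predictor-driven update is expressed here.

Re-running consensus on its own output with the same evidence is a
fixed point: every chosen model wins its locus again and nothing is
altered, which the suite verifies.

## Downstream reports

* `cumulativeAED()` — the empirical distribution of per-gene AED,
  evaluated at every observed value plus 1.0; non-decreasing and ending
  at 1. Comparing curves between releases shows quality changes at a
  glance.
* `quartileEnrichment()` — genes binned into `[0,0.25)`, `[0.25,0.5)`,
  `[0.5,0.75)`, `[0.75,1]` with the fraction carrying a boolean
  attribute per bin. Bins are right-open except the last (so AED 0.25
  falls in the second bin and AED 1 in the last); the edge rule is a
  package convention, stated here because quartile summaries are often
  reported without one. `filterDomainTable()` collapses a (gene, domain)
  table to the boolean after removing reverse-transcriptase, integrase
  and virus-related entries, so transposon ORFs do not inflate apparent
  domain content.
* `reciprocalBestHits()` — mutual best hits between two 12-column BLAST
  tabular files under an inclusive e-value cap (default `1e-6`). Best
  hit = minimal e-value, ties by maximal bit score then lexicographic
  subject id; self-hits ignored. `orthologyByQuartile()` crosses the
  pairs with AED bins and reports the mean partner count over the
  orthologous subset only (genes with at least one partner), flagging
  the degenerate no-ortholog case instead of dividing by zero.

## The synthetic fixture generator

`simulateFixture()` builds complete scenarios with planted ground
truth, so every pipeline stage is testable without downloads. For a
gene with exon union of $L$ bases and target AED $t$, evidence is
constructed analytically: the rightmost $o = \mathrm{round}(L(1-t))$
exon bases plus $L - o$ bases in the downstream intergenic gap, giving
$SN = SP = o/L$ and AED $= 1 - o/L$, within half a base-pair of $t$
(targets infeasible at the gene's granularity are rejected). Genes are
laid out with gaps wider than any evidence overhang, so locus counts
are exactly controllable; targets equal to 1 are planted by emitting no
evidence at all, because non-overlapping evidence would create a
spurious evidence-only locus.

Default conditions: 100 genes of 1–8 exons (50–300 bp exons, 50–400 bp
introns); per-gene target AEDs drawn from Beta(2, 5) (right-skewed, most
mass at low AED, as a reasonably supported genome shows); evidence
redundancy 3; 18% of genes unsupported; evidence-only loci at 18% of
the gene count; and, for two-set scenarios, 62% of supported genes given
a strictly better competing model. The three fractions mirror the
rough proportions seen when a legacy gene set is re-annotated against
modern evidence: roughly three of five models displaced, one of five
unsupported, and novel loci at about one of five. The generator
restores the ambient RNG state, and identical spec + seed reproduce the
fixture byte for byte.

What the simulation does *not* emulate: nucleotide sequence (no splice
sites, codons, or alignment error), partial or chimeric alignments,
nested or overlapping genes, multi-isoform loci, and cross-contig
structure (everything lives on one contig). Passing the recovery tests
therefore demonstrates that the arithmetic, clustering, selection and
bookkeeping are correct under clean planted conditions—not that real
alignments are this well behaved.

## Numerical and degenerate-input choices

* All metrics are exact rational arithmetic on integer base counts; the
  only tolerance anywhere is the fixture generator's ±0.02 granularity
  allowance.
* Empty evidence gives $SN = 0$ by convention (the $|j| = 0$ case), so
  AED degrades smoothly to 1 rather than dividing by zero.
* An empty reference (or prediction) set makes sensitivity (or
  specificity) undefined in `nucleotideStats()`/`exonStats()`; both are
  reported as errors, not NaN.
* Mixed-seqid interval sets are an error in `normalizeIntervals()`;
  disjoint-seqid intersections return 0 with a warning (configurable to
  an error).
* GFF3 parse errors (dangling `Parent`, transcripts with zero exons)
  name the offending feature ids; the BLAST tabular reader reports
  1-based line numbers for malformed rows.

## Problem sizes in the test suite

The suite cross-checks the interval-arithmetic implementations against
brute-force position-set oracles on 1000 random transcript/evidence
instances over 10 kb sequences, clustering against a
connected-components oracle on random instances of up to 50 features,
and full-pipeline bookkeeping recovery on planted scenarios of up to
200 genes—sizes chosen so the whole suite exercises every code path in
a few minutes on a laptop while the oracle comparisons stay exhaustive
per instance.

## Known limitations

* Evidence class is supplied per file by the caller, not inferred from
  GFF3 types; a mixed-class file read through one channel is scored as
  one class.
* The exon-junction-weighted AED variant used by some annotation engines
  (splice-aware weighting) is out of scope; AED here is purely
  positional.
* Eval-style gene- and transcript-level stringencies beyond nucleotide
  and exon are not implemented; isoform flattening conventions are
  documented above and may differ from other tools at multi-isoform
  loci.
* GFF3 FASTA sections and full Sequence Ontology validation are not
  supported; GTF is not read or written.
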