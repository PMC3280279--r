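# aedqc — evidence-based quality control for genome annotations

`aedqc` scores gene models against the experimental evidence aligned
around them, for annotation teams and curators who need to know which
of their thousands of gene models to trust, which to fix first, and
which competing model to keep at each locus. It works on plain GFF3
(gene/mRNA/exon hierarchies and match/match_part evidence alignments),
BLAST tabular hit files, and TSV attribute tables.

## The statistic

Evidence alignments (ESTs, protein homology, mRNA-seq) and gene models
are clustered into loci by transitive genomic overlap. Each transcript
*i* is then compared with the union *j* of evidence positions in its
locus:

    SN  = |i ∩ j| / |j|        (sensitivity; 0 when the locus has no evidence)
    SP  = |i ∩ j| / |i|        (specificity)
    C   = (SN + SP) / 2        (congruency)
    AED = 1 − C                (Annotation Edit Distance)

AED is 0 when the model's exon footprint equals the evidence footprint
and 1 when the model overlaps no evidence; models near 1 are
prioritized for manual review as likely false positives. On top of the
per-transcript score the package provides reference-based
nucleotide/exon sensitivity–specificity comparisons, consensus
selection across competing annotation sets with re-annotation
bookkeeping (kept / replaced / unsupported / evidence-only loci),
cumulative AED distributions, AED-quartile attribute enrichment,
reciprocal-best-hit orthology, and a deterministic fixture simulator
with planted ground truth.

## Worked example

A single-exon transcript at 101–200 scored against one EST alignment
covering 151–270:

```r
library(aedqc)
library(GenomicRanges)

exons <- GRanges("chr1", IRanges(101, 200), "+")
est   <- EvidenceSet(GRangesList(e1 = GRanges("chr1", IRanges(151, 270), "+")),
                     "EST")
as.data.frame(computeAED(exons, est)[, c("sn", "sp", "aed", "n_evidence")])
#>          sn  sp       aed n_evidence
#> 1 0.4166667 0.5 0.5416667          1
```

The 100 bp model shares 50 bases with 120 bp of evidence: the evidence
is 41.7% covered by the model (SN), half the model is confirmed (SP),
and the model sits at distance 0.54 from its evidence — a candidate for
boundary revision, not deletion.

A complete re-annotation run on a simulated scenario:

```r
fx  <- simulateFixture(fixtureSpec(seed = 7, nGenes = 30, nAnnotationSets = 2))
res <- reannotate(list(fx$reference, fx$alternate), fx$evidence)
res$summary
#>   n_input_reference n_altered n_new_loci n_unchanged n_flagged_unsupported
#> 1                30        19          5          11                     5
```

Of 30 reference gene models, 19 were displaced by better-supported
alternates, 11 kept (5 of them flagged as having no evidence support),
and 5 novel loci were synthesized where evidence had no model — and the
counts match the simulator's planted truth table exactly
(`fx$truth$summary`).

The same pipelines are available from a shell via the CLI wrapper
(`inst/scripts/aedqc`), with subcommands `aed`, `compare`, `consensus`,
`report-cdf`, `report-quartiles`, `rbh`, and `simulate`.

See `vignettes/annotation-quality-control.Rmd` for the model,
conventions, and design decisions.

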