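Package: aedqc
Title: Evidence-Based Quality Control and Consensus Management for Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control for genome annotations against aligned
    transcript and protein evidence. Computes per-transcript Annotation
    Edit Distance (AED) by clustering evidence alignments into loci and
    scoring each gene model's congruency with the evidence union;
    evaluates prediction sets against references with nucleotide- and
    exon-level sensitivity, specificity and accuracy; selects a
    consensus model per locus across competing annotation sets with
    re-annotation bookkeeping and review prioritization; and provides
    downstream summaries (cumulative AED distributions, AED-quartile
    attribute enrichment, reciprocal-best-hit orthology). Includes a
    deterministic synthetic-fixture generator with planted ground truth
    and a command-line interface. Input and output are GFF3 gene and
    evidence hierarchies plus tabular hit and attribute files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
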