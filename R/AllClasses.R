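#' AnnotationSet: a labelled collection of gene models
#'
#' Container for one annotation source (a GFF3 file, a simulation, or a
#' consensus run). Each transcript is a non-empty set of exon intervals on
#' one sequence and strand, optionally with CDS intervals, and belongs to
#' a gene. Coordinates are GFF3-style: 1-based, fully closed.
#'
#' @slot label single string naming the set (e.g. `"reference"`).
#' @slot exons [GenomicRanges::GRangesList] of exon ranges, one element
#'   per transcript, named by transcript id.
#' @slot cds [GenomicRanges::GRangesList] parallel to `exons`; elements
#'   may be empty when a transcript has no annotated CDS.
#' @slot txData [S4Vectors::DataFrame] with one row per transcript:
#'   `transcript_id`, `gene_id`, plus any retained GFF3 attributes.
#' @slot provenance single string; source file path or `""`.
#'
#' @seealso [readAnnotations()], [computeAEDSet()], [writeAnnotations()]
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(
    label = "character",
    exons = "CompressedGRangesList",
    cds = "CompressedGRangesList",
    txData = "DataFrame",
    provenance = "character"
  )
)

setValidity("AnnotationSet", function(object) {
  msg <- character(0)
  n <- length(object@exons)
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "'label' must be a single non-NA string")
  ids <- names(object@exons)
  if (n > 0 && (is.null(ids) || anyNA(ids) || anyDuplicated(ids)))
    msg <- c(msg, "exons must be named by unique transcript ids")
  if (nrow(object@txData) != n)
    msg <- c(msg, "txData must have one row per transcript")
  if (n > 0 && !identical(as.character(object@txData$transcript_id), ids))
    msg <- c(msg, "txData$transcript_id must match names(exons)")
  if (length(object@cds) != n)
    msg <- c(msg, "cds must be parallel to exons")
  if (any(elementNROWS(object@exons) == 0L))
    msg <- c(msg, "every transcript must have at least one exon")
  if (n > 0) {
    nseq <- vapply(seq_len(n), function(i) {
      length(unique(as.character(seqnames(object@exons[[i]]))))
    }, integer(1))
    nstr <- vapply(seq_len(n), function(i) {
      length(unique(as.character(strand(object@exons[[i]]))))
    }, integer(1))
    if (any(nseq > 1L) || any(nstr > 1L))
      msg <- c(msg, "all exons of a transcript must share one seqid and strand")
    # CDS must lie within the exon footprint
    has_cds <- which(elementNROWS(object@cds) > 0L)
    for (i in has_cds) {
      out <- GenomicRanges::setdiff(
        reduce(granges(object@cds[[i]]), min.gapwidth = 0L),
        reduce(granges(object@exons[[i]]), min.gapwidth = 0L),
        ignore.strand = TRUE
      )
      if (sum(width(out)) > 0) {
        msg <- c(msg, sprintf("CDS of transcript '%s' extends outside its exons", ids[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' EvidenceSet: aligned experimental evidence
#'
#' Container for evidence alignments (EST, protein, or mRNA-seq) in
#' genome coordinates. Each alignment is a non-empty set of
#' aligned-segment intervals ("parts") on one sequence.
#'
#' @slot parts [GenomicRanges::GRangesList] of aligned-segment ranges,
#'   one element per alignment, named by alignment id.
#' @slot evidenceClass character vector parallel to `parts`; each entry
#'   one of `"EST"`, `"protein"`, `"mRNA-seq"`.
#' @slot score numeric vector parallel to `parts` (NA when absent).
#'
#' @seealso [readEvidence()], [computeAEDSet()]
#' @exportClass EvidenceSet
setClass("EvidenceSet",
  representation(
    parts = "CompressedGRangesList",
    evidenceClass = "character",
    score = "numeric"
  )
)

.EVIDENCE_CLASSES <- c("EST", "protein", "mRNA-seq")

setValidity("EvidenceSet", function(object) {
  msg <- character(0)
  n <- length(object@parts)
  ids <- names(object@parts)
  if (n > 0 && (is.null(ids) || anyNA(ids) || anyDuplicated(ids)))
    msg <- c(msg, "parts must be named by unique alignment ids")
  if (length(object@evidenceClass) != n || length(object@score) != n)
    msg <- c(msg, "evidenceClass and score must be parallel to parts")
  if (n > 0 && !all(object@evidenceClass %in% .EVIDENCE_CLASSES))
    msg <- c(msg, sprintf("evidenceClass values must be one of: %s",
                          paste(.EVIDENCE_CLASSES, collapse = ", ")))
  if (any(elementNROWS(object@parts) == 0L))
    msg <- c(msg, "every alignment must have at least one part")
  if (n > 0) {
    nseq <- vapply(seq_len(n), function(i) {
      length(unique(as.character(seqnames(object@parts[[i]]))))
    }, integer(1))
    if (any(nseq > 1L))
      msg <- c(msg, "all parts of an alignment must share one seqid")
  }
  if (length(msg)) msg else TRUE
})

#' LocusClusters: a single-linkage partition of features into loci
#'
#' Result of clustering transcripts and evidence alignments by transitive
#' genomic overlap. Every feature belongs to exactly one locus; loci never
#' span sequences.
#'
#' @slot membership [S4Vectors::DataFrame] with one row per feature:
#'   `id`, `kind` (`"transcript"` or `"evidence"`), `set` (annotation-set
#'   label or evidence class), `seqid`, `strand`, `locus` (integer id).
#' @slot nLoci integer count of loci.
#'
#' @seealso [buildLoci()], [clusterSingleLinkage()]
#' @exportClass LocusClusters
setClass("LocusClusters",
  representation(membership = "DataFrame", nLoci = "integer")
)

setValidity("LocusClusters", function(object) {
  m <- object@membership
  req <- c("id", "kind", "set", "seqid", "strand", "locus")
  if (!all(req %in% colnames(m)))
    return(sprintf("membership must have columns: %s", paste(req, collapse = ", ")))
  if (nrow(m) > 0 && (anyNA(m$locus) || max(m$locus) > object@nLoci))
    return("locus ids must be in 1..nLoci")
  TRUE
})

#' FixtureSpec: parameters for the synthetic fixture generator
#'
#' Describes a simulated annotation/evidence scenario with planted ground
#' truth. Identical spec and seed give identical outputs.
#'
#' @slot seed integer random seed.
#' @slot nGenes number of reference gene models.
#' @slot exonCountRange integer range (min, max) of exons per gene.
#' @slot exonLengthRange integer range of exon lengths in bp.
#' @slot intronLengthRange integer range of intron lengths in bp.
#' @slot targetAED per-gene target AED values, recycled over genes, or
#'   `NA` to sample each gene's target from a Beta(2, 5) distribution.
#' @slot evidenceRedundancy alignments generated per supported gene.
#' @slot fractionUnsupported fraction of genes given no evidence (AED 1).
#' @slot fractionEvidenceOnly evidence-only loci, as a fraction of nGenes.
#' @slot fractionAltered fraction of genes given a strictly
#'   better-supported competing model (used when nAnnotationSets >= 2).
#' @slot nAnnotationSets 1 (reference only) or 2 (plus an alternate set).
#'
#' @seealso [fixtureSpec()], [simulateFixture()]
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    seed = "integer",
    nGenes = "integer",
    exonCountRange = "integer",
    exonLengthRange = "integer",
    intronLengthRange = "integer",
    targetAED = "numeric",
    evidenceRedundancy = "integer",
    fractionUnsupported = "numeric",
    fractionEvidenceOnly = "numeric",
    fractionAltered = "numeric",
    nAnnotationSets = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@exonLengthRange[1] < 1L) msg <- c(msg, "exon lengths must be positive")
  t <- object@targetAED
  if (!all(is.na(t)) && (any(t < 0, na.rm = TRUE) || any(t > 1, na.rm = TRUE)))
    msg <- c(msg, "targetAED values must lie in [0, 1]")
  for (f in c("fractionUnsupported", "fractionEvidenceOnly", "fractionAltered")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
  }
  if (!object@nAnnotationSets %in% 1:2)
    msg <- c(msg, "nAnnotationSets must be 1 or 2")
  if (length(msg)) msg else TRUE
})
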