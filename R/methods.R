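## Accessors, constructors and show methods for the core containers.

#' Construct an AnnotationSet
#'
#' Low-level constructor; most users will obtain sets from
#' [readAnnotations()] or [simulateFixture()].
#'
#' @param label single string naming the set.
#' @param exons named [GenomicRanges::GRangesList] of exon ranges per
#'   transcript.
#' @param geneId character vector of parent gene ids, parallel to
#'   `exons` (defaults to the transcript ids themselves).
#' @param cds optional named [GenomicRanges::GRangesList] of CDS ranges;
#'   transcripts absent from it get an empty CDS.
#' @param txData optional [S4Vectors::DataFrame] of extra per-transcript
#'   attribute columns.
#' @param provenance source file path or other origin tag.
#' @return An [AnnotationSet-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
#' )
#' AnnotationSet("demo", ex, geneId = "g1")
#' @export
AnnotationSet <- function(label, exons, geneId = names(exons), cds = NULL,
                          txData = NULL, provenance = "") {
  exons <- methods::as(exons, "CompressedGRangesList")
  n <- length(exons)
  ids <- names(exons)
  if (is.null(cds)) {
    cds <- methods::as(GRangesList(lapply(seq_len(n), function(i) GRanges())),
                       "CompressedGRangesList")
    names(cds) <- ids
  } else {
    cds <- methods::as(cds, "CompressedGRangesList")
    full <- methods::as(GRangesList(lapply(seq_len(n), function(i) {
      if (!is.null(names(cds)) && ids[i] %in% names(cds)) granges(cds[[ids[i]]]) else GRanges()
    })), "CompressedGRangesList")
    names(full) <- ids
    cds <- full
  }
  td <- DataFrame(transcript_id = as.character(ids),
                  gene_id = as.character(geneId))
  if (!is.null(txData) && ncol(txData) > 0) {
    extra <- txData[, setdiff(colnames(txData), colnames(td)), drop = FALSE]
    if (ncol(extra) > 0) td <- cbind(td, extra)
  }
  methods::new("AnnotationSet", label = label, exons = exons, cds = cds,
               txData = td, provenance = provenance)
}

#' Construct an EvidenceSet
#'
#' @param parts named [GenomicRanges::GRangesList] of aligned-segment
#'   ranges per alignment.
#' @param evidenceClass evidence class per alignment (`"EST"`,
#'   `"protein"` or `"mRNA-seq"`); recycled if length 1.
#' @param score optional numeric alignment scores.
#' @return An [EvidenceSet-class] object.
#' @examples
#' p <- GenomicRanges::GRangesList(
#'   e1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
#' )
#' EvidenceSet(p, "EST")
#' @export
EvidenceSet <- function(parts, evidenceClass, score = NA_real_) {
  parts <- methods::as(parts, "CompressedGRangesList")
  n <- length(parts)
  if (length(evidenceClass) == 1L) evidenceClass <- rep(evidenceClass, n)
  if (length(score) == 1L) score <- rep(as.numeric(score), n)
  methods::new("EvidenceSet", parts = parts,
               evidenceClass = as.character(evidenceClass), score = score)
}

#' Combine evidence sets
#'
#' @param x,... [EvidenceSet-class] objects to concatenate. Alignment ids
#'   must remain unique after combination.
#' @return A single [EvidenceSet-class].
#' @export
setMethod("c", "EvidenceSet", function(x, ...) {
  objs <- c(list(x), list(...))
  methods::new("EvidenceSet",
    parts = do.call(c, lapply(objs, function(o) o@parts)),
    evidenceClass = unlist(lapply(objs, function(o) o@evidenceClass), use.names = FALSE),
    score = unlist(lapply(objs, function(o) o@score), use.names = FALSE))
})

#' @rdname AnnotationSet-class
#' @export
setMethod("setLabel", "AnnotationSet", function(object) object@label)

#' @rdname AnnotationSet-class
#' @export
setMethod("transcriptIds", "AnnotationSet", function(object) names(object@exons))

#' @rdname AnnotationSet-class
#' @export
setMethod("geneIds", "AnnotationSet", function(object)
  as.character(object@txData$gene_id))

#' @rdname AnnotationSet-class
#' @export
setMethod("exonRanges", "AnnotationSet", function(object) object@exons)

#' @rdname AnnotationSet-class
#' @export
setMethod("cdsRanges", "AnnotationSet", function(object) object@cds)

#' @rdname AnnotationSet-class
#' @export
setMethod("txData", "AnnotationSet", function(object) object@txData)

#' @rdname AnnotationSet-class
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@exons))

#' Subset an AnnotationSet by transcript
#'
#' @param x an [AnnotationSet-class].
#' @param i transcript ids or indices.
#' @param j,...,drop ignored.
#' @return An [AnnotationSet-class] with the selected transcripts.
#' @export
setMethod("[", "AnnotationSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  methods::new("AnnotationSet", label = x@label,
               exons = x@exons[i], cds = x@cds[i],
               txData = x@txData[i, , drop = FALSE],
               provenance = x@provenance)
})

setMethod("show", "AnnotationSet", function(object) {
  seqs <- unique(as.character(unlist(seqnames(object@exons), use.names = FALSE)))
  cat(sprintf("AnnotationSet '%s': %d transcript(s), %d gene(s) on %d seqid(s)\n",
              object@label, length(object),
              length(unique(geneIds(object))), length(seqs)))
  if (length(object) > 0) {
    shown <- head(names(object@exons), 5L)
    cat("  transcripts:", paste(shown, collapse = ", "),
        if (length(object) > 5L) "..." else "", "\n")
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @rdname EvidenceSet-class
#' @param object,x an object.
#' @export
setMethod("alignmentIds", "EvidenceSet", function(object) names(object@parts))

#' @rdname EvidenceSet-class
#' @export
setMethod("evidenceClass", "EvidenceSet", function(object)
  setNames(object@evidenceClass, names(object@parts)))

#' @rdname EvidenceSet-class
#' @export
setMethod("partRanges", "EvidenceSet", function(object) object@parts)

#' @rdname EvidenceSet-class
#' @export
setMethod("length", "EvidenceSet", function(x) length(x@parts))

#' Subset an EvidenceSet by alignment
#'
#' @param x an [EvidenceSet-class].
#' @param i alignment ids or indices.
#' @param j,...,drop ignored.
#' @return An [EvidenceSet-class] with the selected alignments.
#' @export
setMethod("[", "EvidenceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@parts))
  methods::new("EvidenceSet", parts = x@parts[i],
               evidenceClass = x@evidenceClass[i], score = x@score[i])
})

setMethod("show", "EvidenceSet", function(object) {
  tab <- table(object@evidenceClass)
  cat(sprintf("EvidenceSet: %d alignment(s) [%s]\n", length(object),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", ")))
})

#' @rdname LocusClusters-class
#' @param object an object.
#' @export
setMethod("locusMembership", "LocusClusters", function(object) object@membership)

#' @rdname LocusClusters-class
#' @export
setMethod("nLoci", "LocusClusters", function(object) object@nLoci)

setMethod("show", "LocusClusters", function(object) {
  m <- object@membership
  cat(sprintf("LocusClusters: %d locus/loci over %d feature(s) (%d transcript(s), %d evidence)\n",
              object@nLoci, nrow(m), sum(m$kind == "transcript"),
              sum(m$kind == "evidence")))
})
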