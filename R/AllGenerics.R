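#' @rdname AnnotationSet-class
#' @param object,x an object.
#' @export
setGeneric("setLabel", function(object) standardGeneric("setLabel"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("transcriptIds", function(object) standardGeneric("transcriptIds"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("cdsRanges", function(object) standardGeneric("cdsRanges"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("txData", function(object) standardGeneric("txData"))

#' @rdname EvidenceSet-class
#' @export
setGeneric("alignmentIds", function(object) standardGeneric("alignmentIds"))

#' @rdname EvidenceSet-class
#' @export
setGeneric("evidenceClass", function(object) standardGeneric("evidenceClass"))

#' @rdname EvidenceSet-class
#' @export
setGeneric("partRanges", function(object) standardGeneric("partRanges"))

#' @rdname LocusClusters-class
#' @export
setGeneric("locusMembership", function(object) standardGeneric("locusMembership"))

#' @rdname LocusClusters-class
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))
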