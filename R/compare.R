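## Reference-based evaluation of a prediction set: sensitivity,
## specificity and accuracy at nucleotide and exon stringency.
## Strand-aware throughout: opposite-strand overlap never counts, and
## unstranded features only match unstranded ones here.

## flatten a set's exons to one reduced GRanges keeping strand
.flatten_exons <- function(set) {
  ex <- unlist(set@exons, use.names = FALSE)
  if (length(ex) == 0L) return(GRanges())
  reduce(granges(ex), min.gapwidth = 0L, ignore.strand = FALSE)
}

.space_key <- function(gr) paste(as.character(seqnames(gr)), as.character(strand(gr)))

#' Nucleotide-level comparison of two annotation sets
#'
#' Flattens each set's exons to a union of covered positions per
#' seqid/strand and computes
#' `SN = |i n j| / |j|`, `SP = |i n j| / |i|`, `accuracy = (SN + SP)/2`,
#' with `i` the prediction union and `j` the reference union.
#' Overlapping isoform exons are flattened by union first, so
#' multi-isoform sets are well defined.
#'
#' @param pred,ref [AnnotationSet-class] objects (prediction, reference).
#' @return A one-row data.frame: `level`, `sn`, `sp`, `accuracy`.
#' @examples
#' ex <- function(s, e) GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), "+"))
#' p <- AnnotationSet("pred", ex(1, 100))
#' r <- AnnotationSet("ref", ex(21, 140))
#' nucleotideStats(p, r)
#' @export
nucleotideStats <- function(pred, ref) {
  i_gr <- .flatten_exons(pred)
  j_gr <- .flatten_exons(ref)
  j_size <- sum(width(j_gr))
  i_size <- sum(width(i_gr))
  if (j_size == 0) stop("empty reference set: sensitivity is undefined")
  if (i_size == 0) stop("empty prediction set: specificity is undefined")
  o <- 0L
  for (key in intersect(unique(.space_key(i_gr)), unique(.space_key(j_gr)))) {
    o <- o + intersectionSize(i_gr[.space_key(i_gr) == key],
                              j_gr[.space_key(j_gr) == key])
  }
  sn <- o / j_size
  sp <- o / i_size
  data.frame(level = "nucleotide", sn = sn, sp = sp, accuracy = (sn + sp) / 2,
             stringsAsFactors = FALSE)
}

## distinct exon coordinate tuples (seqid, strand, start, end) of a set
.exon_tuples <- function(set) {
  ex <- unlist(set@exons, use.names = FALSE)
  if (length(ex) == 0L) return(character(0))
  unique(paste(as.character(seqnames(ex)), as.character(strand(ex)),
               start(ex), end(ex)))
}

#' Exon-level comparison of two annotation sets
#'
#' An exon counts as matched only when both its start and end equal
#' those of an exon in the other set on the same seqid and strand; a
#' one-base boundary shift fails. Exons are deduplicated by coordinates
#' within each set (shared isoform exons count once).
#' `SN` = matched reference exons / distinct reference exons;
#' `SP` = matched prediction exons / distinct prediction exons.
#'
#' @inheritParams nucleotideStats
#' @return A one-row data.frame: `level`, `sn`, `sp`, `accuracy`.
#' @export
exonStats <- function(pred, ref) {
  ti <- .exon_tuples(pred)
  tj <- .exon_tuples(ref)
  if (length(tj) == 0L) stop("empty reference set: sensitivity is undefined")
  if (length(ti) == 0L) stop("empty prediction set: specificity is undefined")
  nmatch <- length(intersect(ti, tj))
  sn <- nmatch / length(tj)
  sp <- nmatch / length(ti)
  data.frame(level = "exon", sn = sn, sp = sp, accuracy = (sn + sp) / 2,
             stringsAsFactors = FALSE)
}

#' Comparison statistics at both stringencies
#'
#' @inheritParams nucleotideStats
#' @return A two-row data.frame ([nucleotideStats()] then [exonStats()]).
#' @export
compareStats <- function(pred, ref) {
  rbind(nucleotideStats(pred, ref), exonStats(pred, ref))
}

#' Write a comparison report as TSV
#'
#' Rows `(level, sn, sp, accuracy)`, values as percentages to 2 decimals
#' (e.g. `88.48`).
#'
#' @param stats data.frame from [compareStats()].
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeComparisonReport <- function(stats, file) {
  df <- data.frame(
    level = stats$level,
    sn = sprintf("%.2f", 100 * stats$sn),
    sp = sprintf("%.2f", 100 * stats$sp),
    accuracy = sprintf("%.2f", 100 * stats$accuracy),
    stringsAsFactors = FALSE
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
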