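## Interval arithmetic and locus clustering. Coordinates are GFF3-style
## throughout: 1-based, fully closed, so width = end - start + 1.

#' Normalize a set of genomic intervals
#'
#' Sorts intervals and merges overlapping ones. Book-ended intervals
#' (e.g. `[1,10]` and `[11,20]`) are deliberately NOT merged: they cover
#' adjacent but distinct positions, the covered-base count is unaffected,
#' and keeping them separate preserves exon boundaries needed by
#' exon-level metrics.
#'
#' @param x a [GenomicRanges::GRanges] of intervals on a single seqid.
#' @return A sorted, overlap-merged [GenomicRanges::GRanges].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5), c(10, 20)))
#' normalizeIntervals(gr)  # one interval [1,20]
#' @export
normalizeIntervals <- function(x) {
  stopifnot(methods::is(x, "GRanges"))
  sq <- unique(as.character(seqnames(x)))
  if (length(sq) > 1L)
    stop("intervals span multiple seqids (", paste(sq, collapse = ", "),
         "); normalize one seqid at a time")
  reduce(granges(x), min.gapwidth = 0L)
}

#' Count bases covered by a set of intervals
#'
#' The size of the union of positions, i.e. the cardinality terms |i| and
#' |j| of the AED formulas.
#'
#' @param x a [GenomicRanges::GRanges] (any seqids; need not be normalized).
#' @return Integer count of distinct covered positions.
#' @export
coveredBases <- function(x) {
  if (length(x) == 0L) return(0L)
  sum(width(reduce(granges(x), min.gapwidth = 0L, ignore.strand = TRUE)))
}

#' Size of the intersection of two interval sets
#'
#' Computes the number of positions covered by both sets, |i n j|.
#' Strand is ignored: callers decide strand compatibility up front (for
#' AED this is done by locus clustering).
#'
#' @param a,b [GenomicRanges::GRanges] objects.
#' @param differentSeqids what to do when the two sets live on different
#'   seqids: `"warn"` (default) returns 0 with a warning, `"error"` stops.
#' @return Integer base count, symmetric in `a` and `b`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 270))
#' intersectionSize(a, b)  # 50
#' @export
intersectionSize <- function(a, b, differentSeqids = c("warn", "error")) {
  differentSeqids <- match.arg(differentSeqids)
  if (length(a) == 0L || length(b) == 0L) return(0L)
  sa <- unique(as.character(seqnames(a)))
  sb <- unique(as.character(seqnames(b)))
  if (length(intersect(sa, sb)) == 0L) {
    if (differentSeqids == "error")
      stop("interval sets share no seqid: ", paste(sa, collapse = ","),
           " vs ", paste(sb, collapse = ","))
    warning("interval sets share no seqid; intersection is 0")
    return(0L)
  }
  tot <- 0L
  for (sq in intersect(sa, sb)) {
    ra <- reduce(ranges(a[seqnames(a) == sq]), min.gapwidth = 0L)
    rb <- reduce(ranges(b[seqnames(b) == sq]), min.gapwidth = 0L)
    tot <- tot + sum(width(IRanges::intersect(ra, rb)))
  }
  as.integer(tot)
}

## strand compatibility masks for findOverlaps-based clustering
.strand_compatible <- function(s1, s2, strandMode) {
  switch(strandMode,
    ignore = rep(TRUE, length(s1)),
    strict = s1 == s2,
    aware = s1 == s2 | s1 == "*" | s2 == "*"
  )
}

## sweep-line single-linkage over flat interval vectors. Intervals that
## fall in one maximal overlapping run (closed coords: next start <=
## running max end) form a chain of pairwise >= 1 bp overlaps, so their
## features are unioned. Strand policy is applied by sweeping strand-
## compatible subsets; unstranded features participate in both strand
## sweeps under "aware", which also links opposite strands transitively
## through them (matching the pairwise-compatibility closure).
.cluster_flat <- function(st, en, seqid, featIdx, featStrand, n, strandMode) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  ivStrand <- featStrand[featIdx]
  groups <- switch(strandMode,
    ignore = list(rep(TRUE, length(st))),
    aware = list(ivStrand %in% c("+", "*"), ivStrand %in% c("-", "*")),
    strict = list(ivStrand == "+", ivStrand == "-", ivStrand == "*"))
  for (sel in groups) {
    idx <- which(sel)
    if (length(idx) < 2L) next
    for (sq in unique(seqid[idx])) {
      k <- idx[seqid[idx] == sq]
      k <- k[order(st[k], en[k])]
      maxend <- en[k[1L]]
      rep_feat <- featIdx[k[1L]]
      for (m in k[-1L]) {
        if (st[m] <= maxend) {
          link(rep_feat, featIdx[m])
          if (en[m] > maxend) maxend <- en[m]
        } else {
          maxend <- en[m]
          rep_feat <- featIdx[m]
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Single-linkage clustering of features into loci
#'
#' Partitions features (each a set of intervals, e.g. a transcript's
#' exons or an evidence alignment's parts) into maximal groups connected
#' by chains of pairwise overlap of at least `minOverlap` shared bases.
#' Features on different seqids never share a cluster.
#'
#' Strand policy (`strandMode`):
#' * `"aware"` (default): equal strands are compatible, and unstranded
#'   (`*`) features are compatible with either strand — protein
#'   alignments are often reported unstranded.
#' * `"strict"`: strands must be identical (`*` only matches `*`).
#' * `"ignore"`: strand never blocks linkage.
#'
#' @param features a named [GenomicRanges::GRangesList]; each element is
#'   one feature's intervals (one seqid, one strand per feature).
#' @param strandMode `"aware"`, `"strict"`, or `"ignore"`.
#' @param minOverlap minimum number of shared bases for linkage
#'   (default 1).
#' @return Integer vector of cluster ids (1-based, in order of first
#'   appearance), named by feature.
#' @examples
#' fl <- GenomicRanges::GRangesList(
#'   f1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+"),
#'   f2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 150), "+"),
#'   f3 = GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 250), "+")
#' )
#' clusterSingleLinkage(fl)  # f1,f2 -> 1; f3 -> 2
#' @export
clusterSingleLinkage <- function(features,
                                 strandMode = c("aware", "strict", "ignore"),
                                 minOverlap = 1L) {
  strandMode <- match.arg(strandMode)
  features <- methods::as(features, "CompressedGRangesList")
  n <- length(features)
  if (n == 0L) return(setNames(integer(0), character(0)))
  stopifnot(!is.null(names(features)))

  nr <- elementNROWS(features)
  flat <- unlist(features, use.names = FALSE)
  featStrand <- as.character(strand(flat))[cumsum(nr) - nr + 1L]

  if (minOverlap <= 1L) {
    comp <- .cluster_flat(start(flat), end(flat),
                          as.character(seqnames(flat)),
                          rep(seq_len(n), nr), featStrand, n, strandMode)
    return(setNames(comp, names(features)))
  }

  ## wider linkage thresholds need pairwise overlap widths
  hits <- findOverlaps(features, drop.self = TRUE, drop.redundant = TRUE,
                       ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q) && strandMode != "ignore") {
    keep <- .strand_compatible(featStrand[q], featStrand[s], strandMode)
    q <- q[keep]; s <- s[keep]
  }
  if (length(q)) {
    ov <- vapply(seq_along(q), function(k) {
      intersectionSize(features[[q[k]]], features[[s[k]]])
    }, integer(1))
    keep <- ov >= minOverlap
    q <- q[keep]; s <- s[keep]
  }

  ## union-find over the overlap graph
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(q)) {
    ri <- find(q[k]); rj <- find(s[k])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, unique(roots)), names(features))
}
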