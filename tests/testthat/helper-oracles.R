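# Brute-force oracles used to cross-check the interval-arithmetic
# implementations, all working on explicit nucleotide position sets.

# position set (integer vector) covered by a set of closed intervals
posSet <- function(starts, ends) {
  if (length(starts) == 0L) return(integer(0))
  sort(unique(unlist(Map(seq.int, starts, ends))))
}

posSetGR <- function(gr) posSet(GenomicRanges::start(gr), GenomicRanges::end(gr))

# brute-force SN/SP/AED from position sets: i = prediction positions,
# jlist = list of per-alignment position sets (the cluster's evidence)
bruteAED <- function(i_pos, jlist) {
  j_pos <- sort(unique(unlist(jlist)))
  o <- length(intersect(i_pos, j_pos))
  sn <- if (length(j_pos) == 0L) 0 else o / length(j_pos)
  sp <- o / length(i_pos)
  list(sn = sn, sp = sp, aed = 1 - (sn + sp) / 2)
}

# connected components of the pairwise-overlap graph by breadth-first
# search; features = list of (seqid, strand, positions)
bruteComponents <- function(features, strandMode = "aware") {
  n <- length(features)
  compat <- function(a, b) {
    if (a$seqid != b$seqid) return(FALSE)
    ok <- switch(strandMode,
      ignore = TRUE,
      strict = a$strand == b$strand,
      aware = a$strand == b$strand || a$strand == "*" || b$strand == "*")
    ok && length(intersect(a$pos, b$pos)) >= 1L
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in seq_len(n)) {
        if (is.na(comp[v]) && compat(features[[u]], features[[v]])) {
          comp[v] <- cur
          queue <- c(queue, v)
        }
      }
    }
  }
  comp
}

# sort-and-scan oracle for the cumulative distribution
bruteCumulative <- function(aeds) {
  xs <- sort(unique(c(aeds, 1)))
  data.frame(aed = xs,
             fraction = vapply(xs, function(x) sum(aeds <= x) / length(aeds),
                               numeric(1)))
}

# ---- small constructors used across the tests ----------------------------

gr <- function(starts, ends, seqid = "chr1", strand = "+") {
  GenomicRanges::GRanges(seqid, IRanges::IRanges(starts, ends), strand)
}

# annotation set from a list of exon GRanges (names become tx ids)
mkSet <- function(exList, label = "test", geneId = NULL) {
  gl <- methods::as(GenomicRanges::GRangesList(exList), "CompressedGRangesList")
  if (is.null(geneId)) geneId <- sub("\\.t\\d+$", "", names(gl))
  AnnotationSet(label, gl, geneId = geneId)
}

# evidence set from a list of part GRanges (names become alignment ids)
mkEv <- function(partList, class = "EST") {
  EvidenceSet(methods::as(GenomicRanges::GRangesList(partList),
                          "CompressedGRangesList"), class)
}

# random interval set on [1, width]: n intervals of length <= maxlen
randIntervals <- function(n, width = 10000L, maxlen = 500L) {
  s <- sample.int(width - maxlen, n, replace = TRUE)
  e <- s + sample.int(maxlen, n, replace = TRUE) - 1L
  list(starts = s, ends = pmin(e, width))
}
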