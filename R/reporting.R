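## Downstream summaries: cumulative AED distributions, AED-quartile
## attribute enrichment, and reciprocal-best-hit orthology from BLAST
## tabular hit files.

.AED_BIN_LABELS <- c("[0,0.25)", "[0.25,0.5)", "[0.5,0.75)", "[0.75,1]")

.aed_bins <- function(aeds) {
  if (any(aeds < 0 | aeds > 1, na.rm = TRUE) || anyNA(aeds))
    stop("AED values must lie in [0, 1]")
  ## right-open bins except the last, which includes 1
  findInterval(aeds, c(0, 0.25, 0.5, 0.75), rightmost.closed = FALSE)
}

#' Cumulative AED distribution
#'
#' The fraction of genes with AED at or below each observed value,
#' evaluated at every distinct AED (plus 1.0). The curve is
#' non-decreasing and ends at 1 whenever any genes exist; plotted per
#' annotation set, it makes quality improvements between releases
#' directly visible (curves shifted toward low AED are better).
#'
#' @param aeds numeric vector of AED values in `[0, 1]` (typically
#'   per-gene values from [geneAED()]).
#' @return A data.frame with columns `aed` and `fraction` (0 rows for
#'   empty input).
#' @examples
#' cumulativeAED(c(0, 0.5, 1, 1))
#' @export
cumulativeAED <- function(aeds) {
  if (length(aeds) == 0L)
    return(data.frame(aed = numeric(0), fraction = numeric(0)))
  .aed_bins(aeds)  # validates range
  xs <- sort(unique(c(aeds, 1)))
  data.frame(aed = xs,
             fraction = vapply(xs, function(x) mean(aeds <= x), numeric(1)))
}

#' Attribute enrichment across AED quartiles
#'
#' Splits genes into the four AED bins `[0,0.25)`, `[0.25,0.5)`,
#' `[0.5,0.75)`, `[0.75,1]` and reports the fraction of
#' attribute-positive genes per bin (e.g. the fraction carrying a Pfam
#' domain, or retained in a later release). Genes absent from the
#' attribute table count as negative.
#'
#' @param aeds named numeric vector of per-gene AEDs in `[0, 1]`.
#' @param attributes either a logical vector named by gene id, or a
#'   two-column data.frame (gene id, value) whose value column is
#'   coerced to logical (accepts TRUE/FALSE, 1/0, "yes"/"no").
#' @return A data.frame with one row per bin: `bin`, `aed_min`,
#'   `aed_max`, `n_genes`, `n_with_attribute`, `fraction`.
#' @export
quartileEnrichment <- function(aeds, attributes) {
  stopifnot(!is.null(names(aeds)))
  att <- .as_attribute_vector(attributes)
  pos <- names(aeds) %in% names(att)[att]
  bin <- .aed_bins(aeds)
  n <- tabulate(bin, nbins = 4L)
  npos <- vapply(1:4, function(b) sum(pos[bin == b]), integer(1))
  data.frame(
    bin = .AED_BIN_LABELS,
    aed_min = c(0, 0.25, 0.5, 0.75),
    aed_max = c(0.25, 0.5, 0.75, 1),
    n_genes = n,
    n_with_attribute = npos,
    fraction = ifelse(n > 0, npos / n, 0),
    stringsAsFactors = FALSE
  )
}

.as_attribute_vector <- function(attributes) {
  if (is.data.frame(attributes)) {
    stopifnot(ncol(attributes) >= 2L)
    v <- attributes[[2L]]
    if (!is.logical(v)) {
      if (is.numeric(v)) v <- v != 0
      else v <- tolower(as.character(v)) %in% c("true", "t", "yes", "y", "1")
    }
    setNames(v, as.character(attributes[[1L]]))
  } else {
    stopifnot(is.logical(attributes), !is.null(names(attributes)))
    attributes
  }
}

#' Collapse a (gene, domain) table to a per-gene boolean attribute
#'
#' Applies a keyword exclusion list (case-insensitive substring match on
#' the domain description) before collapsing, mirroring the common
#' practice of removing reverse transcriptase, integrase, and
#' virus-related domains so transposon ORFs do not inflate apparent
#' domain content; unknown/uncharacterized/NULL entries are dropped too.
#'
#' @param domains data.frame with gene ids in column 1 and domain names/
#'   descriptions in column 2.
#' @param exclude character vector of keywords to exclude.
#' @param dropUnnamed also drop entries matching
#'   unknown/uncharacterized/NULL (default TRUE).
#' @return Logical vector named by gene id: TRUE when the gene retains
#'   at least one domain after filtering. All genes present in the input
#'   table appear.
#' @export
filterDomainTable <- function(domains,
                              exclude = c("reverse transcriptase",
                                          "integrase", "virus"),
                              dropUnnamed = TRUE) {
  stopifnot(is.data.frame(domains), ncol(domains) >= 2L)
  gene <- as.character(domains[[1L]])
  dom <- as.character(domains[[2L]])
  drop <- rep(FALSE, length(dom))
  for (kw in exclude) drop <- drop | grepl(kw, dom, ignore.case = TRUE)
  if (dropUnnamed)
    drop <- drop | grepl("^(unknown|uncharacteri[sz]ed|NULL)$", dom,
                         ignore.case = TRUE) | is.na(dom) | dom == ""
  keep <- tapply(!drop, gene, any)
  out <- as.logical(keep)
  names(out) <- names(keep)
  out[unique(gene)]
}

## ---- reciprocal best hits ------------------------------------------------

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column BLAST tabular hit file
#'
#' Standard `-outfmt 6` columns: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' Malformed rows are reported with their line number.
#'
#' @param file path to a tab-separated hit file (no header).
#' @return A data.frame with the 12 standard columns.
#' @export
readBlastTab <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), .BLAST_COLS))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed hit row (expected 12 tab-separated fields) at line ",
         bad[1L], " of ", file)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- .BLAST_COLS
  for (cn in .BLAST_COLS[3:12]) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !all(is.na(df[[cn]])))
      stop("non-numeric value in column '", cn, "' at line ",
           which(is.na(v))[1L], " of ", file)
    df[[cn]] <- v
  }
  df
}

## best hit per query: min e-value, then max bitscore, then lexicographic
## subject id; self-hits removed first
.best_hits <- function(hits) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two datasets
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best hit in the A-vs-B
#' table, `a` is `b`'s best hit in the B-vs-A table, and both best hits
#' have e-value at or below `maxEvalue` (default 1e-6, inclusive). The
#' best hit per query is the minimal e-value, ties broken by maximal bit
#' score then lexicographic subject id; self-hits are ignored. RBH pairs
#' are a pragmatic proxy for orthology.
#'
#' @param hitsAB,hitsBA hit tables (data.frames from [readBlastTab()] or
#'   file paths) for A queried against B and B against A.
#' @param maxEvalue inclusive e-value threshold.
#' @return A data.frame of pairs: `id_a`, `id_b`, `evalue_ab`,
#'   `evalue_ba`, sorted by `id_a`.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, maxEvalue = 1e-6) {
  if (is.character(hitsAB)) hitsAB <- readBlastTab(hitsAB)
  if (is.character(hitsBA)) hitsBA <- readBlastTab(hitsBA)
  ab <- .best_hits(hitsAB)
  ba <- .best_hits(hitsBA)
  ab <- ab[ab$evalue <= maxEvalue, , drop = FALSE]
  ba <- ba[ba$evalue <= maxEvalue, , drop = FALSE]
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0),
                      stringsAsFactors = FALSE))
  back <- setNames(as.character(ba$sseqid), ba$qseqid)
  mutual <- !is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid
  ab <- ab[mutual, , drop = FALSE]
  out <- data.frame(
    id_a = as.character(ab$qseqid),
    id_b = as.character(ab$sseqid),
    evalue_ab = ab$evalue,
    evalue_ba = ba$evalue[match(ab$sseqid, ba$qseqid)],
    stringsAsFactors = FALSE
  )
  out[order(out$id_a), , drop = FALSE]
}

#' Orthology rate across AED quartiles
#'
#' For each AED bin, the fraction of genes with at least one
#' reciprocal-best-hit partner in any partner species, plus the mean
#' number of partners per gene over the orthologous subset (genes with
#' at least one partner). When no gene has a partner the mean is
#' undefined and reported as 0 with the `mean_defined` attribute FALSE.
#'
#' @param aeds named numeric vector of per-gene AEDs in `[0, 1]`.
#' @param rbhPairs a data.frame from [reciprocalBestHits()] (gene ids in
#'   `id_a`), or a list of them (one per partner species).
#' @return A data.frame with one row per bin: `bin`, `n_genes`,
#'   `n_orthologous`, `fraction`; attributes `mean_orthologs` (numeric)
#'   and `mean_defined` (logical).
#' @export
orthologyByQuartile <- function(aeds, rbhPairs) {
  stopifnot(!is.null(names(aeds)))
  if (is.data.frame(rbhPairs)) rbhPairs <- list(rbhPairs)
  counts <- setNames(numeric(length(aeds)), names(aeds))
  for (p in rbhPairs) {
    tab <- table(factor(as.character(p$id_a), levels = names(aeds)))
    counts <- counts + as.numeric(tab)
  }
  has <- counts > 0
  bin <- .aed_bins(aeds)
  n <- tabulate(bin, nbins = 4L)
  nor <- vapply(1:4, function(b) sum(has[bin == b]), integer(1))
  out <- data.frame(
    bin = .AED_BIN_LABELS,
    n_genes = n,
    n_orthologous = nor,
    fraction = ifelse(n > 0, nor / n, 0),
    stringsAsFactors = FALSE
  )
  if (any(has)) {
    attr(out, "mean_orthologs") <- mean(counts[has])
    attr(out, "mean_defined") <- TRUE
  } else {
    attr(out, "mean_orthologs") <- 0
    attr(out, "mean_defined") <- FALSE
  }
  out
}
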