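## Deterministic fixture generator with planted ground truth. Genes are
## laid out along one synthetic contig with generous intergenic gaps so
## locus counts are exactly controllable; evidence for each supported
## gene is constructed analytically so the planted AED is recovered by
## computeAEDSet (exactly, up to base-pair granularity).
##
## Construction for a gene with exon union i of L bases and target AED t:
## take the rightmost o = round(L * (1 - t)) bases of i and append
## (L - o) bases in the downstream intergenic gap. The evidence union j
## then has L bases, |i n j| = o, so SN = SP = o/L and
## AED = 1 - o/L ~ t (granularity 1/(2L)). t = 1 (or o = 0) is planted
## by emitting no evidence at all: any non-overlapping evidence would
## form its own (evidence-only) locus and corrupt locus bookkeeping.

#' Construct a FixtureSpec
#'
#' @param seed integer random seed; identical spec + seed give
#'   byte-identical outputs.
#' @param nGenes number of reference gene models.
#' @param exonCountRange,exonLengthRange,intronLengthRange integer
#'   (min, max) ranges for gene structure, in exons / bp.
#' @param targetAED per-gene target AED in `[0, 1]` (recycled), or `NA`
#'   (default) to sample targets from Beta(2, 5) — a right-skewed
#'   distribution concentrating mass at low AED, the shape a
#'   well-supported genome's AED profile takes.
#' @param evidenceRedundancy alignments per supported gene (redundant
#'   copies of the same footprint, as deep EST sampling produces).
#' @param fractionUnsupported fraction of genes planted with no evidence
#'   (true AED 1). Default 0.18, a typical share of unsupported models
#'   in a legacy annotation set.
#' @param fractionEvidenceOnly evidence-only loci as a fraction of
#'   `nGenes` (candidate novel genes). Default 0.18.
#' @param fractionAltered fraction of genes that receive a strictly
#'   better-supported competing model in the alternate set (only used
#'   when `nAnnotationSets = 2`). Default 0.62, a typical share of
#'   legacy models displaced during evidence-driven re-annotation.
#' @param nAnnotationSets 1 (reference only) or 2 (reference plus an
#'   alternate set for consensus runs).
#' @return A validated [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 1L, nGenes = 100L,
                        exonCountRange = c(1L, 8L),
                        exonLengthRange = c(50L, 300L),
                        intronLengthRange = c(50L, 400L),
                        targetAED = NA_real_,
                        evidenceRedundancy = 3L,
                        fractionUnsupported = 0.18,
                        fractionEvidenceOnly = 0.18,
                        fractionAltered = 0.62,
                        nAnnotationSets = 1L) {
  methods::new("FixtureSpec",
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    exonCountRange = as.integer(exonCountRange),
    exonLengthRange = as.integer(exonLengthRange),
    intronLengthRange = as.integer(intronLengthRange),
    targetAED = as.numeric(targetAED),
    evidenceRedundancy = as.integer(evidenceRedundancy),
    fractionUnsupported = fractionUnsupported,
    fractionEvidenceOnly = fractionEvidenceOnly,
    fractionAltered = fractionAltered,
    nAnnotationSets = as.integer(nAnnotationSets))
}

## the rightmost `o` covered bases of a normalized interval set
.rightmost_bases <- function(ivs, o) {
  keep <- list()
  for (k in rev(seq_len(nrow(ivs)))) {
    if (o <= 0) break
    w <- ivs$end[k] - ivs$start[k] + 1L
    take <- min(w, o)
    keep[[length(keep) + 1L]] <- c(ivs$end[k] - take + 1L, ivs$end[k])
    o <- o - take
  }
  keep <- rev(keep)
  data.frame(start = vapply(keep, `[`, numeric(1), 1L),
             end = vapply(keep, `[`, numeric(1), 2L))
}

#' Generate a synthetic fixture with planted ground truth
#'
#' See [fixtureSpec()] for the scenario parameters. All outputs live on
#' one synthetic contig (`"ctg1"`); genes are separated by gaps larger
#' than any evidence overhang, so clusters never merge across genes.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir optional directory; when given, the fixture is also
#'   written as GFF3/TSV files (`reference.gff3`, `alternate.gff3`,
#'   `evidence.gff3`, `attributes.tsv`, `hits_ab.tsv`, `hits_ba.tsv`,
#'   `truth_genes.tsv`, `truth_summary.tsv`).
#' @return A list: `reference` ([AnnotationSet-class]), `alternate`
#'   ([AnnotationSet-class] or NULL), `evidence` ([EvidenceSet-class]),
#'   `attributes` (data.frame gene_id/has_domain), `hitsAB`/`hitsBA`
#'   (BLAST tabular data.frames), and `truth` (list with `genes`,
#'   `summary`, `rbhPairs`).
#' @examples
#' fx <- simulateFixture(fixtureSpec(seed = 7, nGenes = 10))
#' fx$truth$summary
#' @export
simulateFixture <- function(spec, dir = NULL) {
  stopifnot(methods::is(spec, "FixtureSpec"))
  methods::validObject(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec@seed)

  n <- spec@nGenes
  seqid <- "ctg1"
  targets <- if (all(is.na(spec@targetAED))) round(rbeta(n, 2, 5), 3)
    else rep(spec@targetAED, length.out = n)

  nUnsup <- round(spec@fractionUnsupported * n)
  unsup <- sort(sample.int(n, nUnsup))
  targets[unsup] <- 1

  ## gene structures laid out left to right
  gene <- vector("list", n)
  cursor <- 1000L
  for (g in seq_len(n)) {
    ne <- sample(seq(spec@exonCountRange[1], spec@exonCountRange[2]), 1L)
    el <- sample(seq(spec@exonLengthRange[1], spec@exonLengthRange[2]), ne,
                 replace = TRUE)
    il <- if (ne > 1) sample(seq(spec@intronLengthRange[1],
                                 spec@intronLengthRange[2]), ne - 1L,
                             replace = TRUE) else integer(0)
    st <- cursor + c(0L, cumsum(el[-ne] + il))
    en <- st + el - 1L
    L <- sum(el)
    strand <- sample(c("+", "-"), 1L)
    gene[[g]] <- list(id = sprintf("gene%04d", g), tx = sprintf("gene%04d.t1", g),
                      start = st, end = en, L = L, strand = strand)
    ## gap large enough for the evidence overhang (up to L bases) plus slack
    cursor <- max(en) + 10L + L + 200L
  }

  ## plant evidence so that the analytically computed AED equals the target
  ev_parts <- list()
  ev_ids <- character(0)
  planted <- numeric(n)
  classes_cycle <- .EVIDENCE_CLASSES
  for (g in seq_len(n)) {
    gn <- gene[[g]]
    t <- targets[g]
    o <- round(gn$L * (1 - t))
    achieved <- 1 - o / gn$L
    if (abs(achieved - t) > 0.02)
      stop(sprintf(
        "target AED %.3f infeasible for gene of %d exon bases (closest %.3f)",
        t, gn$L, achieved))
    if (o <= 0) {  # target within tolerance of 1: no evidence, AED 1 exactly
      planted[g] <- 1
      targets[g] <- 1
      next
    }
    planted[g] <- achieved
    ivs <- .rightmost_bases(data.frame(start = gn$start, end = gn$end), o)
    overhang <- gn$L - o
    if (overhang > 0) {
      tail_start <- max(gn$end) + 10L
      ivs <- rbind(ivs, data.frame(start = tail_start,
                                   end = tail_start + overhang - 1L))
    }
    for (r in seq_len(spec@evidenceRedundancy)) {
      eid <- sprintf("%s.ev%d", gn$id, r)
      ev_ids <- c(ev_ids, eid)
      ev_parts[[eid]] <- GRanges(seqid, IRanges(ivs$start, ivs$end), gn$strand)
    }
  }
  planted[unsup] <- 1
  ## genes whose target rounded to zero overlap are unsupported too
  unsup_eff <- which(planted >= 1)
  ev_class <- classes_cycle[(seq_along(ev_ids) - 1L) %% 3L + 1L]

  ## evidence-only loci: candidate novel genes with no model
  nEO <- round(spec@fractionEvidenceOnly * n)
  for (k in seq_len(nEO)) {
    w1 <- sample(200:600, 1L)
    w2 <- sample(200:600, 1L)
    s1 <- cursor
    ## two book-ended-free overlapping segments forming one alignment
    eid <- sprintf("novelEvidence%03d", k)
    ev_ids <- c(ev_ids, eid)
    ev_parts[[eid]] <- GRanges(seqid,
      IRanges(c(s1, s1 + w1 + 50L), c(s1 + w1 - 1L, s1 + w1 + 50L + w2 - 1L)),
      sample(c("+", "-"), 1L))
    ev_class <- c(ev_class, "EST")
    cursor <- s1 + w1 + 50L + w2 + 500L
  }

  ev_gl <- if (length(ev_parts)) GRangesList(ev_parts)[ev_ids] else GRangesList()
  evidence <- EvidenceSet(methods::as(ev_gl, "CompressedGRangesList"), ev_class)

  ## reference annotation set
  ref_ex <- lapply(gene, function(gn)
    GRanges(seqid, IRanges(gn$start, gn$end), gn$strand))
  names(ref_ex) <- vapply(gene, `[[`, character(1), "tx")
  reference <- AnnotationSet(
    "reference", methods::as(GRangesList(ref_ex), "CompressedGRangesList"),
    geneId = vapply(gene, `[[`, character(1), "id"))

  ## alternate set: for altered genes, a model equal to the evidence
  ## footprint (AED 0), strictly better than the reference's planted AED
  alternate <- NULL
  altered <- integer(0)
  if (spec@nAnnotationSets >= 2L) {
    eligible <- setdiff(which(planted > 0 & planted < 1), unsup_eff)
    nAlt <- min(round(spec@fractionAltered * n), length(eligible))
    altered <- sort(sample(eligible, nAlt))
    if (nAlt > 0) {
      alt_ex <- lapply(altered, function(g) {
        first_ev <- sprintf("%s.ev1", gene[[g]]$id)
        granges(ev_parts[[first_ev]])
      })
      names(alt_ex) <- sprintf("alt%04d.t1", altered)
      alternate <- AnnotationSet(
        "alternate", methods::as(GRangesList(alt_ex), "CompressedGRangesList"),
        geneId = sprintf("alt%04d", altered))
    }
  }

  ## per-gene attribute table (domain content tracks evidence support)
  attributes <- data.frame(
    gene_id = vapply(gene, `[[`, character(1), "id"),
    has_domain = planted < 0.5,
    stringsAsFactors = FALSE
  )

  ## orthology hit tables: ortholog probability falls with AED quartile
  orth_prob <- c(0.94, 0.80, 0.50, 0.26)
  bin <- findInterval(planted, c(0, 0.25, 0.5, 0.75))
  is_orth <- runif(n) < orth_prob[bin]
  partner <- sprintf("B%04d", seq_len(n))
  mk_hit <- function(q, s, e, bits) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = 300, mismatch = 5,
               gapopen = 1, qstart = 1, qend = 300, sstart = 1, send = 300,
               evalue = e, bitscore = bits, stringsAsFactors = FALSE)
  }
  hitsAB <- list(); hitsBA <- list()
  for (g in seq_len(n)) {
    gid <- gene[[g]]$id
    if (is_orth[g]) {
      e1 <- 10^-sample(20:80, 1L)
      hitsAB[[length(hitsAB) + 1L]] <- mk_hit(gid, partner[g], e1, 500)
      hitsBA[[length(hitsBA) + 1L]] <- mk_hit(partner[g], gid, e1 * 10, 480)
      ## a decoy second-best hit in each direction
      decoy <- partner[if (g < n) g + 1L else 1L]
      hitsAB[[length(hitsAB) + 1L]] <- mk_hit(gid, decoy, e1 * 1e6, 120)
    } else if (runif(1) < 0.5) {
      ## weak hit above the e-value threshold: never an RBH
      hitsAB[[length(hitsAB) + 1L]] <- mk_hit(gid, partner[g], 1e-3, 40)
    }
  }
  empty_hits <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)),
                                .BLAST_COLS)
  hitsAB <- if (length(hitsAB)) do.call(rbind, hitsAB) else empty_hits
  hitsBA <- if (length(hitsBA)) do.call(rbind, hitsBA) else empty_hits

  truth_genes <- data.frame(
    gene_id = vapply(gene, `[[`, character(1), "id"),
    transcript_id = vapply(gene, `[[`, character(1), "tx"),
    aed_true = planted,
    unsupported = seq_len(n) %in% unsup_eff,
    altered = seq_len(n) %in% altered,
    orthologous = is_orth,
    stringsAsFactors = FALSE
  )
  truth_summary <- data.frame(
    n_input_reference = n,
    n_altered = length(altered),
    n_new_loci = nEO,
    n_unchanged = n - length(altered),
    n_flagged_unsupported = length(unsup_eff)
  )
  truth_rbh <- data.frame(
    id_a = truth_genes$gene_id[is_orth],
    id_b = partner[is_orth],
    stringsAsFactors = FALSE
  )

  out <- list(reference = reference, alternate = alternate,
              evidence = evidence, attributes = attributes,
              hitsAB = hitsAB, hitsBA = hitsBA,
              truth = list(genes = truth_genes, summary = truth_summary,
                           rbhPairs = truth_rbh))
  if (!is.null(dir)) .write_fixture(out, dir)
  out
}

.write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAnnotations(fx$reference, file.path(dir, "reference.gff3"))
  if (!is.null(fx$alternate))
    writeAnnotations(fx$alternate, file.path(dir, "alternate.gff3"))
  writeEvidence(fx$evidence, file.path(dir, "evidence.gff3"))
  write.table(fx$attributes, file.path(dir, "attributes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fx$hitsAB, file.path(dir, "hits_ab.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(fx$hitsBA, file.path(dir, "hits_ba.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(fx$truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fx$truth$summary, file.path(dir, "truth_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an EvidenceSet as GFF3 match/match_part features
#'
#' Top-level feature types follow the evidence class
#' (`expressed_sequence_match` for EST, `protein_match` for protein,
#' `cDNA_match` for mRNA-seq) with `match_part` children.
#'
#' @param evidence an [EvidenceSet-class].
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeEvidence <- function(evidence, file) {
  type_of <- c(EST = "expressed_sequence_match",
               protein = "protein_match",
               `mRNA-seq` = "cDNA_match")
  rows <- list()
  ids <- alignmentIds(evidence)
  for (i in seq_along(ids)) {
    p <- evidence@parts[[i]]
    sq <- as.character(seqnames(p))[1L]
    st <- as.character(strand(p))[1L]
    top <- GRanges(sq, IRanges(min(start(p)), max(end(p))), st,
                   type = type_of[[evidence@evidenceClass[i]]],
                   ID = ids[i], Parent = CharacterList(character(0)))
    kids <- granges(p)
    mcols(kids) <- DataFrame(type = "match_part", ID = NA_character_,
                             Parent = CharacterList(rep(list(ids[i]), length(kids))))
    rows[[length(rows) + 1L]] <- c(top, kids)
  }
  out <- if (length(rows)) do.call(c, rows) else {
    z <- GRanges()
    mcols(z) <- DataFrame(type = character(0), ID = character(0),
                          Parent = CharacterList())
    z
  }
  out$source <- "aedqc"
  mcols(out) <- mcols(out)[, c("source", setdiff(names(mcols(out)), "source"))]
  rtracklayer::export(out, file, format = "gff3")
  invisible(file)
}
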