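## Consensus selection across competing annotation sets: cluster all
## candidate transcripts and evidence into loci, keep the candidate most
## consistent with the evidence (minimal AED) per locus, synthesize
## models for evidence-only loci, and keep the re-annotation books.

#' Build loci from annotation sets and evidence
#'
#' Single-linkage clusters every transcript (from every supplied set)
#' together with every evidence alignment; each connected group of
#' overlapping features is one locus. A transcript belongs to exactly
#' one locus.
#'
#' @param sets a list of [AnnotationSet-class] objects (>= 1). Transcript
#'   ids must be unique across sets.
#' @param evidence an [EvidenceSet-class], or NULL for none.
#' @param strandMode,minOverlap clustering policy, see
#'   [clusterSingleLinkage()].
#' @return A [LocusClusters-class].
#' @export
buildLoci <- function(sets, evidence = NULL,
                      strandMode = c("aware", "strict", "ignore"),
                      minOverlap = 1L) {
  strandMode <- match.arg(strandMode)
  if (methods::is(sets, "AnnotationSet")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, methods::is, logical(1), "AnnotationSet")))
  if (is.null(evidence))
    evidence <- EvidenceSet(GRangesList(), character(0), numeric(0))

  tx_ids <- unlist(lapply(sets, transcriptIds), use.names = FALSE)
  if (anyDuplicated(tx_ids))
    stop("transcript ids are not unique across annotation sets: ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))

  feats <- do.call(c, c(lapply(sets, exonRanges), list(evidence@parts)))
  kind <- c(rep("transcript", length(tx_ids)), rep("evidence", length(evidence)))
  setlab <- c(unlist(lapply(sets, function(s) rep(setLabel(s), length(s))),
                     use.names = FALSE),
              evidence@evidenceClass)
  cl <- clusterSingleLinkage(feats, strandMode = strandMode, minOverlap = minOverlap)
  first_of <- function(gl, fun) vapply(seq_along(gl), function(i)
    as.character(fun(gl[[i]])[1L]), character(1))
  m <- DataFrame(
    id = names(feats),
    kind = kind,
    set = setlab,
    seqid = if (length(feats)) first_of(feats, seqnames) else character(0),
    strand = if (length(feats)) first_of(feats, strand) else character(0),
    locus = unname(cl)
  )
  methods::new("LocusClusters", membership = m,
               nLoci = if (nrow(m)) max(m$locus) else 0L)
}

## exon-base counts per transcript across sets (tie-break criterion)
.exon_base_counts <- function(sets) {
  unlist(lapply(sets, function(s) {
    vapply(seq_along(s@exons), function(i) coveredBases(s@exons[[i]]), integer(1)) |>
      setNames(transcriptIds(s))
  }))
}

#' Select the consensus model at every locus
#'
#' Per locus the candidate transcript with minimal AED is chosen ("most
#' consistent with the evidence"). Ties are broken by (1) larger
#' exon-base count, (2) source-set priority in the order the sets were
#' supplied, (3) lexicographic transcript id. A locus whose chosen model
#' still has AED at or above `reviewThreshold` is flagged for manual
#' review with status `"unsupported"`; otherwise the status is
#' `"kept_unchanged"` when the chosen model comes from the designated
#' reference set's candidates at that locus and `"replaced"` when it
#' displaces them (or the locus has no reference candidate).
#'
#' @param loci a [LocusClusters-class] from [buildLoci()].
#' @param records combined AED record table covering every candidate
#'   transcript (see [consensusRecords()]), with a `source_set` column.
#' @param sets the same list of [AnnotationSet-class] objects given to
#'   [buildLoci()]; set order defines source priority.
#' @param referenceLabel label of the reference set (default: the first
#'   set's label).
#' @param reviewThreshold AED at or above which the chosen model is
#'   flagged (default 1.0 = no evidence support; 0.95 is a useful
#'   setting when the AED distribution spikes near 1).
#' @return A [S4Vectors::DataFrame] of locus decisions: `locus_id`,
#'   `seqid`, `chosen_id`, `chosen_set`, `chosen_gene`, `chosen_aed`,
#'   `status`, `review_flag`, `candidate_ids`, `candidate_aeds`,
#'   `candidate_sets`, `ref_gene_ids`.
#' @export
selectConsensus <- function(loci, records, sets,
                            referenceLabel = NULL, reviewThreshold = 1.0) {
  if (methods::is(sets, "AnnotationSet")) sets <- list(sets)
  if (is.null(referenceLabel)) referenceLabel <- setLabel(sets[[1L]])
  m <- locusMembership(loci)
  tx <- m[m$kind == "transcript", , drop = FALSE]
  stopifnot(all(tx$id %in% records$transcript_id))
  rec_idx <- match(tx$id, records$transcript_id)
  aed <- records$aed[rec_idx]
  gene <- as.character(records$gene_id[rec_idx])
  bases <- .exon_base_counts(sets)[tx$id]
  prio <- match(tx$set, vapply(sets, setLabel, character(1)))

  lids <- sort(unique(tx$locus))
  dec <- lapply(lids, function(L) {
    sel <- which(tx$locus == L)
    ord <- sel[order(aed[sel], -bases[sel], prio[sel], tx$id[sel])]
    ch <- ord[1L]
    is_ref <- tx$set[sel] == referenceLabel
    review <- aed[ch] >= reviewThreshold
    status <- if (review) "unsupported"
      else if (any(is_ref) && tx$set[ch] == referenceLabel) "kept_unchanged"
      else "replaced"
    list(locus_id = L, seqid = tx$seqid[ch], chosen_id = tx$id[ch],
         chosen_set = tx$set[ch], chosen_gene = gene[ch],
         chosen_aed = aed[ch], status = status, review_flag = review,
         candidate_ids = tx$id[sel], candidate_aeds = aed[sel],
         candidate_sets = tx$set[sel],
         ref_gene_ids = unique(gene[sel][is_ref]))
  })
  DataFrame(
    locus_id = vapply(dec, `[[`, integer(1), "locus_id"),
    seqid = vapply(dec, `[[`, character(1), "seqid"),
    chosen_id = vapply(dec, `[[`, character(1), "chosen_id"),
    chosen_set = vapply(dec, `[[`, character(1), "chosen_set"),
    chosen_gene = vapply(dec, `[[`, character(1), "chosen_gene"),
    chosen_aed = vapply(dec, `[[`, numeric(1), "chosen_aed"),
    status = vapply(dec, `[[`, character(1), "status"),
    review_flag = vapply(dec, `[[`, logical(1), "review_flag"),
    candidate_ids = CharacterList(lapply(dec, `[[`, "candidate_ids")),
    candidate_aeds = NumericList(lapply(dec, `[[`, "candidate_aeds")),
    candidate_sets = CharacterList(lapply(dec, `[[`, "candidate_sets")),
    ref_gene_ids = CharacterList(lapply(dec, `[[`, "ref_gene_ids"))
  )
}

#' Detect evidence-only loci and synthesize candidate models
#'
#' Loci containing evidence but no candidate transcript indicate regions
#' where the evidence suggests a gene that no set annotates. For each, a
#' model is synthesized whose exons are the overlap-merged union of the
#' locus's evidence parts (book-ended segments stay separate), and its
#' AED against its own cluster is reported (0 by construction: the model
#' equals the evidence footprint).
#'
#' @param loci a [LocusClusters-class] from [buildLoci()].
#' @param evidence the [EvidenceSet-class] given to [buildLoci()].
#' @param idPrefix prefix for synthesized model ids.
#' @return A list with `decisions` (a [S4Vectors::DataFrame] with
#'   status `"evidence_only"`, same columns as [selectConsensus()]) and
#'   `models` (an [AnnotationSet-class] of synthesized models, label
#'   `"evidence_only"`).
#' @export
detectEvidenceOnlyLoci <- function(loci, evidence, idPrefix = "novel") {
  m <- locusMembership(loci)
  has_tx <- unique(m$locus[m$kind == "transcript"])
  eo <- setdiff(unique(m$locus[m$kind == "evidence"]), has_tx)
  eo <- sort(eo)
  if (length(eo) == 0L) {
    empty <- AnnotationSet("evidence_only",
                           methods::as(GRangesList(), "CompressedGRangesList"))
    dec <- selectConsensus(
      methods::new("LocusClusters", membership = m[0, ], nLoci = 0L),
      .empty_aed_records(), list(empty))
    return(list(decisions = dec, models = empty))
  }
  ev_ids <- m$id[m$kind == "evidence"]
  ev_locus <- m$locus[m$kind == "evidence"]

  exlist <- list()
  rows <- list()
  for (k in seq_along(eo)) {
    L <- eo[k]
    ids <- ev_ids[ev_locus == L]
    parts <- unlist(evidence@parts[ids], use.names = FALSE)
    model <- reduce(granges(parts), min.gapwidth = 0L, ignore.strand = TRUE)
    strand(model) <- as.character(strand(parts))[1L]
    mid <- sprintf("%s-%d", idPrefix, L)
    exlist[[mid]] <- model
    rec <- .aed_one(model, evidence@parts[ids])
    rows[[k]] <- list(locus_id = L, seqid = as.character(seqnames(model))[1L],
                      chosen_id = mid, chosen_aed = rec$aed,
                      candidate_ids = ids, candidate_aeds = rep(NA_real_, length(ids)))
  }
  models <- AnnotationSet("evidence_only",
                          methods::as(GRangesList(exlist), "CompressedGRangesList"))
  dec <- DataFrame(
    locus_id = vapply(rows, `[[`, integer(1), "locus_id"),
    seqid = vapply(rows, `[[`, character(1), "seqid"),
    chosen_id = vapply(rows, `[[`, character(1), "chosen_id"),
    chosen_set = rep("evidence_only", length(rows)),
    chosen_gene = vapply(rows, `[[`, character(1), "chosen_id"),
    chosen_aed = vapply(rows, `[[`, numeric(1), "chosen_aed"),
    status = rep("evidence_only", length(rows)),
    review_flag = rep(FALSE, length(rows)),
    candidate_ids = CharacterList(lapply(rows, `[[`, "candidate_ids")),
    candidate_aeds = NumericList(lapply(rows, `[[`, "candidate_aeds")),
    candidate_sets = CharacterList(lapply(rows, function(r)
      rep("evidence", length(r$candidate_ids)))),
    ref_gene_ids = CharacterList(lapply(rows, function(r) character(0)))
  )
  list(decisions = dec, models = models)
}

#' Summarize a re-annotation run
#'
#' Counts reference gene models by outcome. Every reference gene is
#' either left unchanged (its own transcript was chosen at its locus) or
#' altered (displaced by a better-supported candidate), so
#' `n_altered + n_unchanged = n_input_reference` on every run. New loci
#' are decisions with no reference candidate (evidence-only loci and
#' loci annotated only by alternate sets). Flagged reference genes sit
#' at loci whose chosen model met the review threshold.
#'
#' @param decisions decision table ([selectConsensus()] output,
#'   optionally rbind-ed with [detectEvidenceOnlyLoci()] decisions).
#' @return A one-row data.frame: `n_input_reference`, `n_altered`,
#'   `n_new_loci`, `n_unchanged`, `n_flagged_unsupported`.
#' @export
summarizeReannotation <- function(decisions) {
  ref_genes <- unique(unlist(decisions$ref_gene_ids, use.names = FALSE))
  unchanged <- flagged <- character(0)
  for (i in seq_len(nrow(decisions))) {
    rg <- decisions$ref_gene_ids[[i]]
    if (length(rg) == 0L) next
    if (decisions$chosen_gene[i] %in% rg)
      unchanged <- c(unchanged, decisions$chosen_gene[i])
    if (decisions$review_flag[i]) flagged <- c(flagged, rg)
  }
  n_ref <- length(ref_genes)
  n_unchanged <- length(unique(unchanged))
  data.frame(
    n_input_reference = n_ref,
    n_altered = n_ref - n_unchanged,
    n_new_loci = sum(elementNROWS(decisions$ref_gene_ids) == 0L),
    n_unchanged = n_unchanged,
    n_flagged_unsupported = length(unique(flagged))
  )
}

#' Rank annotations for manual review
#'
#' Sorts AED records from worst supported to best (descending AED;
#' curation effort goes to likely false positives first) and flags
#' records at or above the threshold. Ties keep a stable order by
#' transcript id.
#'
#' @param records AED record table from [computeAEDSet()].
#' @param threshold AED at or above which a record is flagged
#'   (default 1.0).
#' @return The reordered records with a logical `flagged` column.
#' @export
prioritizeForReview <- function(records, threshold = 1.0) {
  ord <- order(-records$aed, as.character(records$transcript_id))
  out <- records[ord, , drop = FALSE]
  out$flagged <- out$aed >= threshold
  out
}

#' Run a full re-annotation
#'
#' Convenience pipeline: computes AED for every candidate transcript of
#' every set against the shared evidence, builds loci, selects the
#' consensus model per locus, synthesizes models for evidence-only loci,
#' and summarizes the bookkeeping. The consensus annotation set contains
#' the chosen model of every locus (non-redundant by construction:
#' chosen models come from distinct loci).
#'
#' @param sets a list of [AnnotationSet-class] objects; the first (or
#'   `referenceLabel`) is the reference whose genes are tracked as
#'   kept/altered.
#' @param evidence an [EvidenceSet-class].
#' @param referenceLabel label of the reference set.
#' @param reviewThreshold see [selectConsensus()].
#' @param includeEvidenceOnly synthesize models at evidence-only loci
#'   (default TRUE).
#' @param ... further arguments passed to [computeAEDSet()] and
#'   [buildLoci()] (`strandMode`, `minOverlap`).
#' @return A list: `records` (combined AED records with `source_set`),
#'   `loci`, `decisions` (consensus plus evidence-only), `summary`
#'   ([summarizeReannotation()] output), and `consensus`
#'   (an [AnnotationSet-class], label `"consensus"`).
#' @export
reannotate <- function(sets, evidence, referenceLabel = NULL,
                       reviewThreshold = 1.0, includeEvidenceOnly = TRUE,
                       ...) {
  if (methods::is(sets, "AnnotationSet")) sets <- list(sets)
  if (is.null(referenceLabel)) referenceLabel <- setLabel(sets[[1L]])
  records <- consensusRecords(sets, evidence, ...)
  loci <- buildLoci(sets, evidence, ...)
  decisions <- selectConsensus(loci, records, sets,
                               referenceLabel = referenceLabel,
                               reviewThreshold = reviewThreshold)
  eo <- detectEvidenceOnlyLoci(loci, evidence)
  if (includeEvidenceOnly && length(eo$models) > 0)
    decisions <- rbind(decisions, eo$decisions)

  ## assemble the consensus set from the winning candidates
  all_tx <- do.call(c, lapply(sets, function(s) {
    gl <- s@exons
    gl
  }))
  gene_of <- unlist(lapply(sets, function(s)
    setNames(geneIds(s), transcriptIds(s))))
  chosen <- decisions$chosen_id[decisions$status != "evidence_only"]
  cons_ex <- all_tx[chosen]
  cons_gene <- gene_of[chosen]
  if (includeEvidenceOnly && length(eo$models) > 0) {
    cons_ex <- c(cons_ex, eo$models@exons)
    cons_gene <- c(cons_gene, setNames(transcriptIds(eo$models),
                                       transcriptIds(eo$models)))
  }
  consensus <- AnnotationSet("consensus", cons_ex, geneId = unname(cons_gene))
  list(records = records, loci = loci, decisions = decisions,
       summary = summarizeReannotation(decisions), consensus = consensus)
}

#' AED records for all candidate sets against shared evidence
#'
#' Runs [computeAEDSet()] on each set with the same evidence and
#' combines the results, adding a `source_set` column.
#'
#' @param sets a list of [AnnotationSet-class] objects.
#' @param evidence an [EvidenceSet-class].
#' @param ... passed to [computeAEDSet()].
#' @return A combined [S4Vectors::DataFrame] of AED records.
#' @export
consensusRecords <- function(sets, evidence, ...) {
  if (methods::is(sets, "AnnotationSet")) sets <- list(sets)
  recs <- lapply(sets, function(s) {
    r <- computeAEDSet(s, evidence, ...)
    r$source_set <- rep(setLabel(s), nrow(r))
    r
  })
  do.call(rbind, recs)
}

#' Write locus decisions as TSV
#'
#' @param decisions decision table from [selectConsensus()] /
#'   [reannotate()].
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeDecisions <- function(decisions, file) {
  df <- data.frame(
    locus_id = decisions$locus_id,
    seqid = decisions$seqid,
    chosen_id = decisions$chosen_id,
    chosen_set = decisions$chosen_set,
    chosen_aed = sprintf("%.4f", decisions$chosen_aed),
    status = decisions$status,
    review_flag = decisions$review_flag,
    n_candidates = elementNROWS(decisions$candidate_ids),
    candidate_ids = vapply(decisions$candidate_ids, paste, character(1),
                           collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
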