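## GFF3 input/output for gene-annotation hierarchies and evidence
## alignments, built on rtracklayer. Only gene/mRNA/exon/CDS (and the
## common transcript-type synonyms) participate in annotation parsing;
## other feature types are counted and skipped.

.TX_TYPES <- c("mRNA", "transcript")
.MATCH_TYPES <- c("match", "expressed_sequence_match", "protein_match",
                  "cDNA_match", "EST_match", "translated_nucleotide_match",
                  "nucleotide_match")

.import_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  if (is.null(mcols(gr)$ID)) mcols(gr)$ID <- rep(NA_character_, length(gr))
  if (is.null(mcols(gr)$Parent)) {
    mcols(gr)$Parent <- CharacterList(rep(list(character(0)), length(gr)))
  }
  gr
}

## one row per (feature, parent) link
.expand_parents <- function(gr) {
  np <- elementNROWS(gr$Parent)
  idx <- rep(seq_along(gr), pmax(np, 0L))
  out <- gr[idx]
  out$parent_id <- unlist(gr$Parent, use.names = FALSE)
  out
}

#' Read gene annotations from GFF3
#'
#' Parses a GFF3 gene/mRNA/exon(/CDS) hierarchy into an
#' [AnnotationSet-class]. Transcript-level rows may be of type `mRNA`,
#' `transcript`, or any type whose Parent is a gene and which has exon
#' children (real-world GFF3 dialects vary). A gene with exon children
#' but no transcript children is wrapped in an implicit single
#' transcript named `<gene>.t1`. Feature types taking no part in the
#' hierarchy are skipped with a message reporting their count.
#' Gzip-compressed input is accepted.
#'
#' @param file path to a GFF3 file (optionally gzipped).
#' @param label label for the resulting set (default: file base name).
#' @return An [AnnotationSet-class].
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1"), gff)
#' readAnnotations(gff, "demo")
#' @export
readAnnotations <- function(file, label = NULL) {
  if (is.null(label)) label <- sub("\\.(gff3?|gff3\\.gz|gff\\.gz)$", "", basename(file))
  gr <- .import_gff3(file)
  type <- as.character(gr$type)
  id <- as.character(gr$ID)

  gene_rows <- which(type == "gene")
  gene_ids <- id[gene_rows]
  if (anyNA(gene_ids)) stop("gene row without an ID attribute")

  exon_rows <- .expand_parents(gr[type == "exon"])
  cds_rows <- .expand_parents(gr[type == "CDS"])
  exon_parents <- unique(exon_rows$parent_id)

  ## transcript-level rows: known types, or gene children that own exons
  cand <- which(!(type %in% c("gene", "exon", "CDS")) & !is.na(id))
  is_tx <- type[cand] %in% .TX_TYPES |
    (id[cand] %in% exon_parents &
       vapply(cand, function(i) any(gr$Parent[[i]] %in% gene_ids), logical(1)))
  tx_rows <- cand[is_tx]
  tx_ids <- id[tx_rows]
  if (anyDuplicated(tx_ids))
    stop("duplicated transcript ID(s): ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))

  tx_gene <- vapply(tx_rows, function(i) {
    p <- gr$Parent[[i]]
    p <- p[p %in% gene_ids]
    if (length(p)) p[1L] else id[i]  # orphan transcript: acts as its own gene
  }, character(1))

  n_ignored <- sum(!(type %in% c("gene", "exon", "CDS")) & !(seq_along(gr) %in% tx_rows) &
                     !(seq_along(gr) %in% gene_rows))
  if (n_ignored > 0)
    message("readAnnotations: ignored ", n_ignored,
            " feature row(s) of types outside the gene/mRNA/exon/CDS hierarchy")

  ## implicit transcripts: genes with direct exon children and no transcripts
  genes_with_tx <- unique(tx_gene)
  implicit_genes <- intersect(setdiff(gene_ids, genes_with_tx), exon_parents)
  bad <- intersect(intersect(gene_ids, genes_with_tx), exon_parents)
  if (length(bad))
    stop("gene(s) with both transcript children and direct exon children: ",
         paste(bad, collapse = ", "))
  if (length(implicit_genes)) {
    imp_tx <- paste0(implicit_genes, ".t1")
    tx_ids <- c(tx_ids, imp_tx)
    tx_gene <- c(tx_gene, implicit_genes)
    exon_rows$parent_id[exon_rows$parent_id %in% implicit_genes] <-
      paste0(exon_rows$parent_id[exon_rows$parent_id %in% implicit_genes], ".t1")
    cds_rows$parent_id[cds_rows$parent_id %in% implicit_genes] <-
      paste0(cds_rows$parent_id[cds_rows$parent_id %in% implicit_genes], ".t1")
  }

  dang <- setdiff(unique(c(exon_rows$parent_id, cds_rows$parent_id)), tx_ids)
  if (length(dang))
    stop("exon/CDS row(s) with dangling Parent reference: ",
         paste(dang, collapse = ", "))
  no_exon <- setdiff(tx_ids, unique(exon_rows$parent_id))
  if (length(no_exon))
    stop("transcript(s) with zero exons: ", paste(no_exon, collapse = ", "))

  split_by_tx <- function(rows) {
    f <- factor(rows$parent_id, levels = tx_ids)
    gl <- methods::as(S4Vectors::split(granges(rows), f), "CompressedGRangesList")
    GenomicRanges::sort(gl)
  }
  exons <- split_by_tx(exon_rows)
  cds <- split_by_tx(cds_rows)

  ## retain simple character attributes from the transcript rows
  extra <- NULL
  if (length(tx_rows)) {
    mc <- mcols(gr)[tx_rows, , drop = FALSE]
    keep <- setdiff(colnames(mc), c("source", "type", "score", "phase", "ID", "Parent"))
    keep <- keep[vapply(keep, function(cn) is.atomic(mc[[cn]]), logical(1))]
    if (length(keep)) {
      extra <- mc[, keep, drop = FALSE]
      if (length(implicit_genes))
        extra <- rbind(extra, DataFrame(lapply(extra, function(col)
          rep(NA, length(implicit_genes)))))
    }
  }

  set <- AnnotationSet(label, exons, geneId = tx_gene, cds = cds,
                       txData = extra, provenance = as.character(file))
  methods::validObject(set)
  set
}

#' Read evidence alignments from GFF3
#'
#' Parses match/match_part (or `expressed_sequence_match`,
#' `protein_match`, `cDNA_match`, ...) hierarchies into an
#' [EvidenceSet-class]. A top-level match with no parts becomes a
#' single-part alignment over its own span; bare segment rows sharing an
#' ID (with no Parent) are grouped into one alignment. The evidence
#' class is supplied by the caller per file, mirroring separate
#' EST/protein/mRNA-seq input channels, rather than inferred from GFF3
#' types.
#'
#' @param file path to a GFF3 file (optionally gzipped).
#' @param evidenceClass `"EST"`, `"protein"`, or `"mRNA-seq"`.
#' @return An [EvidenceSet-class] (possibly empty).
#' @export
readEvidence <- function(file, evidenceClass = c("EST", "protein", "mRNA-seq")) {
  evidenceClass <- match.arg(evidenceClass)
  gr <- .import_gff3(file)
  if (length(gr) == 0L)
    return(EvidenceSet(GRangesList(), character(0), numeric(0)))
  has_parent <- elementNROWS(gr$Parent) > 0L
  tops <- gr[!has_parent]
  kids <- .expand_parents(gr[has_parent])

  top_ids <- as.character(tops$ID)
  top_ids[is.na(top_ids)] <- sprintf(".anon%d", which(is.na(top_ids)))
  dang <- setdiff(unique(kids$parent_id), top_ids)
  if (length(dang))
    stop("match_part row(s) with dangling Parent reference: ",
         paste(dang, collapse = ", "))

  uids <- unique(top_ids)
  parts <- lapply(uids, function(uid) {
    p <- granges(kids[kids$parent_id == uid])
    if (length(p) == 0L) {
      rows <- which(top_ids == uid)
      ## multiple bare rows sharing an ID are themselves the parts
      p <- granges(tops[rows])
    }
    GenomicRanges::sort(p)
  })
  names(parts) <- uids
  score <- vapply(uids, function(uid) {
    s <- tops$score[top_ids == uid]
    s <- s[!is.na(s)]
    if (length(s)) as.numeric(s[1L]) else NA_real_
  }, numeric(1))
  ev <- EvidenceSet(methods::as(GRangesList(parts), "CompressedGRangesList"),
                    evidenceClass, score)
  methods::validObject(ev)
  ev
}

.format_aed <- function(x) sprintf("%.2f", x)

#' Write an AnnotationSet as GFF3
#'
#' Emits a gene/mRNA/exon(/CDS) hierarchy. When AED records are
#' supplied, each mRNA row carries an `_AED=<value>` attribute (2
#' decimals; the leading underscore keeps the attribute in the
#' MAKER-compatible namespace). Extra per-transcript attributes can be
#' attached via `txAttrs`. The read-write-read round trip preserves ids,
#' coordinates, hierarchy, and `_AED` values.
#'
#' @param set an [AnnotationSet-class].
#' @param file output path.
#' @param aedRecords optional AED record table from [computeAEDSet()];
#'   matched to transcripts by `transcript_id`.
#' @param txAttrs optional named list/DataFrame of extra per-transcript
#'   character attributes (names = attribute keys), each a vector named
#'   by transcript id.
#' @param source value for GFF3 column 2 (default `"aedqc"`).
#' @return Invisibly, the output path.
#' @export
writeAnnotations <- function(set, file, aedRecords = NULL, txAttrs = NULL,
                             source = "aedqc") {
  stopifnot(methods::is(set, "AnnotationSet"))
  tx_ids <- transcriptIds(set)
  g_ids <- geneIds(set)
  aed <- setNames(rep(NA_character_, length(tx_ids)), tx_ids)
  if (!is.null(aedRecords) && length(tx_ids)) {
    m <- match(tx_ids, aedRecords$transcript_id)
    aed[!is.na(m)] <- .format_aed(aedRecords$aed[m[!is.na(m)]])
  }

  rows <- list()
  for (g in unique(g_ids)) {
    sel <- which(g_ids == g)
    gex <- unlist(set@exons[sel], use.names = FALSE)
    sq <- as.character(seqnames(gex))[1L]
    st <- as.character(strand(gex))[1L]
    grow <- GRanges(sq, IRanges(min(start(gex)), max(end(gex))), st,
                    type = "gene", ID = g, Parent = CharacterList(character(0)),
                    tx = NA_character_)
    txrows <- lapply(sel, function(i) {
      ex <- set@exons[[i]]
      GRanges(sq, IRanges(min(start(ex)), max(end(ex))),
              as.character(strand(ex))[1L],
              type = "mRNA", ID = tx_ids[i], Parent = CharacterList(g),
              tx = tx_ids[i])
    })
    exrows <- lapply(sel, function(i) {
      ex <- granges(set@exons[[i]])
      mcols(ex) <- DataFrame(type = "exon", ID = NA_character_,
                             Parent = CharacterList(rep(list(tx_ids[i]), length(ex))),
                             tx = NA_character_)
      ex
    })
    cdsrows <- lapply(sel, function(i) {
      cd <- granges(set@cds[[i]])
      if (length(cd) == 0L) return(NULL)
      mcols(cd) <- DataFrame(type = "CDS", ID = NA_character_,
                             Parent = CharacterList(rep(list(tx_ids[i]), length(cd))),
                             tx = NA_character_)
      cd
    })
    rows[[length(rows) + 1L]] <-
      do.call(c, c(list(grow), txrows, exrows, Filter(Negate(is.null), cdsrows)))
  }
  out <- if (length(rows)) {
    do.call(c, rows)
  } else {
    z <- GRanges()
    mcols(z) <- DataFrame(type = character(0), ID = character(0),
                          Parent = CharacterList(), tx = character(0))
    z
  }

  ## per-transcript attributes land on the mRNA rows only
  out$`_AED` <- ifelse(is.na(out$tx), NA_character_, aed[out$tx])
  if (!is.null(txAttrs)) {
    for (key in names(txAttrs)) {
      v <- txAttrs[[key]]
      mcols(out)[[key]] <- ifelse(is.na(out$tx), NA_character_,
                                  as.character(v[out$tx]))
    }
  }
  ## retained parse-time attributes (skip ones we already emit)
  td <- txData(set)
  for (cn in setdiff(colnames(td), c("transcript_id", "gene_id"))) {
    if (cn %in% names(mcols(out)) || (!is.null(txAttrs) && cn %in% names(txAttrs)))
      next
    v <- setNames(as.character(td[[cn]]), tx_ids)
    mcols(out)[[cn]] <- ifelse(is.na(out$tx), NA_character_, v[out$tx])
  }
  out$tx <- NULL
  out$source <- source
  mcols(out) <- mcols(out)[, c("source", setdiff(names(mcols(out)), "source"))]
  rtracklayer::export(out, file, format = "gff3")
  invisible(file)
}
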