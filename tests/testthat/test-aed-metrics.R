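# Per-transcript Annotation Edit Distance against clustered evidence.

test_that("worked single-exon example: SN 0.4167, SP 0.5, AED 0.5417", {
  ev <- mkEv(list(e1 = gr(151, 270)))
  rec <- computeAED(gr(101, 200), ev)
  # pre-verified by the position-set oracle
  oracle <- bruteAED(posSet(101, 200), list(posSet(151, 270)))
  expect_equal(oracle$aed, 0.5416667, tolerance = 1e-6)
  expect_equal(rec$sn, 50 / 120)
  expect_equal(rec$sp, 0.5)
  expect_equal(rec$congruency, (50 / 120 + 0.5) / 2)
  expect_equal(rec$aed, oracle$aed)
})

test_that("AED boundary semantics: 0 iff footprints agree, 1 iff no overlap", {
  exons <- gr(c(1, 101), c(50, 150))
  # evidence identical to the exon footprint -> complete agreement
  rec0 <- computeAED(exons, mkEv(list(e = gr(c(1, 101), c(50, 150)))))
  expect_equal(rec0$aed, 0)
  expect_equal(rec0$sn, 1); expect_equal(rec0$sp, 1)
  # no overlapping evidence -> no support
  rec1 <- computeAED(exons, mkEv(list(e = gr(500, 600))))
  expect_equal(rec1$aed, 1)
  expect_equal(rec1$n_evidence, 0L)
  # empty evidence set
  rec2 <- computeAED(exons, mkEv(setNames(list(), character(0))))
  expect_equal(rec2$aed, 1)
  # partial overlap is strictly between the boundaries
  rec3 <- computeAED(exons, mkEv(list(e = gr(25, 50))))
  expect_gt(rec3$aed, 0); expect_lt(rec3$aed, 1)
  # same covered bases but different footprint is not 0
  rec4 <- computeAED(exons, mkEv(list(e = gr(c(1, 90), c(50, 139)))))
  expect_gt(rec4$aed, 0)
  # empty exon set violates the transcript contract
  expect_error(computeAED(GenomicRanges::GRanges(), mkEv(list(e = gr(1, 10)))),
               "empty exon")
})

test_that("interval-arithmetic AED equals the position-set oracle on random instances", {
  set.seed(2024)
  for (rep in 1:250) {
    ne <- sample(1:5, 1)
    iv <- randIntervals(ne, width = 10000L, maxlen = 400L)
    exons <- gr(iv$starts, iv$ends)
    nev <- sample(0:4, 1)
    evl <- lapply(seq_len(nev), function(k) {
      e <- randIntervals(sample(1:3, 1), width = 10000L, maxlen = 600L)
      gr(e$starts, e$ends)
    })
    names(evl) <- sprintf("e%d", seq_len(nev))
    rec <- computeAED(exons, mkEv(evl))
    # oracle: evidence restricted to the transcript's transitive cluster
    i_pos <- posSetGR(exons)
    feats <- c(list(list(seqid = "chr1", strand = "+", pos = i_pos)),
               lapply(evl, function(g)
                 list(seqid = "chr1", strand = "+", pos = posSetGR(g))))
    comp <- bruteComponents(feats)
    in_cluster <- which(comp[-1L] == comp[1L])
    want <- bruteAED(i_pos, lapply(evl[in_cluster], posSetGR))
    expect_equal(rec$aed, want$aed, tolerance = 1e-12, info = paste("rep", rep))
    expect_equal(rec$sn, want$sn, tolerance = 1e-12)
    expect_equal(rec$sp, want$sp, tolerance = 1e-12)
    expect_equal(rec$n_evidence, length(in_cluster))
  }
})

test_that("AED is symmetric under exchanging annotation and evidence", {
  set.seed(55)
  for (rep in 1:100) {
    a <- randIntervals(sample(1:4, 1)); b <- randIntervals(sample(1:4, 1))
    ga <- gr(a$starts, a$ends); gb <- gr(b$starts, b$ends)
    if (intersectionSize(ga, gb) == 0L) next  # both sides are AED 1 anyway
    d1 <- computeAED(ga, mkEv(list(e = gb)))$aed
    d2 <- computeAED(gb, mkEv(list(e = ga)))$aed
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("enlarging the overlap with |i|,|j| fixed never increases AED", {
  # i = [1,1000]; j slides from disjoint to identical: overlap grows
  aeds <- vapply(seq(0, 1000, by = 100), function(shift) {
    computeAED(gr(1, 1000), mkEv(list(e = gr(1001 - shift, 2000 - shift))))$aed
  }, numeric(1))
  expect_true(all(diff(aeds) <= 1e-12))
  expect_equal(aeds[1], 1)       # no overlap
  expect_equal(aeds[length(aeds)], 0)  # identical footprints
})

test_that("cluster locality: evidence elsewhere on the chromosome is invisible", {
  exons <- gr(101, 200)
  near <- mkEv(list(e1 = gr(151, 270)))
  far <- mkEv(list(e1 = gr(151, 270), far1 = gr(100000, 101000)))
  expect_equal(computeAED(exons, near)$aed, computeAED(exons, far)$aed)
  expect_equal(computeAED(exons, far)$n_evidence, 1L)
})

test_that("computeAEDSet scores each transcript against its own locus", {
  set <- mkSet(list(g1.t1 = gr(101, 200), g2.t1 = gr(1001, 1100)))
  ev <- mkEv(list(e1 = gr(101, 200)))
  rec <- computeAEDSet(set, ev)
  expect_equal(rec$aed, c(0, 1))
  expect_equal(rec$n_evidence, c(1L, 0L))

  # determinism under input shuffling
  set2 <- mkSet(list(g2.t1 = gr(1001, 1100), g1.t1 = gr(101, 200)))
  rec2 <- computeAEDSet(set2, ev)
  m <- match(rec$transcript_id, rec2$transcript_id)
  expect_equal(rec2$aed[m], rec$aed)

  # transcripts of one gene aggregate by the best isoform
  set3 <- mkSet(list(g1.t1 = gr(101, 200), g1.t2 = gr(101, 260)),
                geneId = c("g1", "g1"))
  rec3 <- computeAEDSet(set3, ev)
  ga <- geneAED(rec3)
  expect_equal(unname(ga["g1"]), min(rec3$aed))
  expect_equal(unname(geneAED(rec)), rec$aed)  # single-tx genes pass through
})

test_that("evidence pooling: pooled beats per-class when classes jointly cover", {
  # EST covers the left half, protein the right half of a 200 bp exon
  exons <- gr(1, 200)
  ev <- c(mkEv(list(est = gr(1, 120)), "EST"),
          mkEv(list(pro = gr(81, 200)), "protein"))
  set <- mkSet(list(g1.t1 = exons))
  pooled <- computeAEDSet(set, ev, classMode = "pooled")
  percl <- computeAEDSet(set, ev, classMode = "per-class")
  expect_equal(pooled$aed, 0)  # joint footprint equals the exon
  expect_gt(percl$aed, 0)
  expect_lte(pooled$aed, percl$aed)
  expect_true(percl$evidence_class %in% c("EST", "protein"))

  set.seed(9)
  # property on random jointly-covering splits
  for (rep in 1:50) {
    cut1 <- sample(50:150, 1); cut2 <- sample(50:150, 1)
    ev2 <- c(mkEv(list(est = gr(1, max(cut1, cut2))), "EST"),
             mkEv(list(pro = gr(min(cut1, cut2), 200)), "protein"))
    expect_lte(computeAEDSet(set, ev2, classMode = "pooled")$aed,
               computeAEDSet(set, ev2, classMode = "per-class")$aed + 1e-12)
  }
})

test_that("the per-alignment-sum |j| mode dilutes SN under redundant evidence", {
  exons <- gr(1, 100)
  ev <- mkEv(list(e1 = gr(1, 100), e2 = gr(1, 100), e3 = gr(1, 100)))
  expect_equal(computeAED(exons, ev)$aed, 0)  # union mode: perfect agreement
  rec <- computeAED(exons, ev, jMode = "sum")
  expect_equal(rec$sn, 100 / 300)  # triplicated evidence dilutes SN
  expect_gt(rec$aed, 0)
  partial <- mkEv(list(full = gr(1, 100), half = gr(1, 50)))
  expect_equal(computeAED(exons, partial)$aed, 0)
  expect_gt(computeAED(exons, partial, jMode = "sum")$aed, 0)
})

test_that("CDS-restricted mode scores coding coordinates", {
  exons <- GenomicRanges::GRangesList(t1 = gr(c(1, 101), c(80, 200)))
  cds <- GenomicRanges::GRangesList(t1 = gr(c(21, 101), c(80, 160)))
  set <- AnnotationSet("cds", exons, geneId = "g1", cds = cds)
  ev <- mkEv(list(e = gr(c(21, 101), c(80, 160))))
  expect_equal(computeAEDSet(set, ev, useCDS = TRUE)$aed, 0)
  expect_gt(computeAEDSet(set, ev, useCDS = FALSE)$aed, 0)
})

test_that("AED report TSV has the documented shape", {
  set <- mkSet(list(g1.t1 = gr(101, 200)))
  rec <- computeAEDSet(set, mkEv(list(e1 = gr(151, 270))))
  f <- tempfile(fileext = ".tsv")
  writeAEDReport(rec, f)
  tab <- read.delim(f, colClasses = "character")
  expect_equal(colnames(tab), c("transcript_id", "gene_id", "seqid", "strand",
                                "sn", "sp", "aed", "n_evidence"))
  expect_equal(tab$aed, "0.5417")
})
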