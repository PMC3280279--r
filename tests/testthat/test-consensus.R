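# Locus building, consensus selection, re-annotation bookkeeping,
# review prioritization.

test_that("buildLoci pools transcripts from all sets with evidence", {
  ref <- mkSet(list(r1.t1 = gr(101, 200)), "reference")
  alt <- mkSet(list(a1.t1 = gr(121, 240)), "alternate")
  ev <- mkEv(list(e1 = gr(150, 400)))
  loci <- buildLoci(list(ref, alt), ev)
  expect_s4_class(loci, "LocusClusters")
  expect_equal(nLoci(loci), 1L)
  m <- locusMembership(loci)
  expect_setequal(m$id, c("r1.t1", "a1.t1", "e1"))

  # disjoint transcripts: one locus each
  two <- mkSet(list(x.t1 = gr(1, 100), y.t1 = gr(1000, 1100)), "two")
  expect_equal(nLoci(buildLoci(list(two))), 2L)

  # chain A-B, B-C with A,C disjoint merges into one locus
  chain <- mkSet(list(A.t1 = gr(1, 100), B.t1 = gr(90, 210), C.t1 = gr(200, 300)),
                 "chain")
  expect_equal(nLoci(buildLoci(list(chain))), 1L)

  # duplicate transcript ids across sets are rejected
  dup <- mkSet(list(r1.t1 = gr(500, 600)), "dup")
  expect_error(buildLoci(list(ref, dup)), "not unique")
})

test_that("consensus picks the minimal-AED candidate with documented tie-breaks", {
  ref <- mkSet(list(r1.t1 = gr(101, 220)), "reference")
  alt <- mkSet(list(a1.t1 = gr(101, 200)), "alternate")
  ev <- mkEv(list(e1 = gr(101, 200)))
  res <- reannotate(list(ref, alt), ev)
  d <- res$decisions
  expect_equal(nrow(d), 1L)
  expect_equal(d$chosen_id, "a1.t1")  # AED 0 beats the longer reference
  expect_equal(d$status, "replaced")
  expect_false(d$review_flag)

  # AED tie: larger exon-base count wins
  loci <- buildLoci(list(mkSet(list(b.t1 = gr(1, 300), s.t1 = gr(1, 400)), "tie",
                               geneId = c("b", "s"))))
  rec <- S4Vectors::DataFrame(transcript_id = c("b.t1", "s.t1"),
                              gene_id = c("b", "s"), aed = c(0.3, 0.3),
                              source_set = "tie")
  dec <- selectConsensus(loci, rec, list(mkSet(list(b.t1 = gr(1, 300),
                                                    s.t1 = gr(1, 400)), "tie",
                                               geneId = c("b", "s"))))
  expect_equal(dec$chosen_id, "s.t1")  # 400 > 300 exon bases

  # full tie: source-set priority order, then lexicographic id
  eq <- mkSet(list(z.t1 = gr(1, 100), a.t1 = gr(1, 100)), "eq",
              geneId = c("z", "a"))
  loci2 <- buildLoci(list(eq))
  rec2 <- S4Vectors::DataFrame(transcript_id = c("z.t1", "a.t1"),
                               gene_id = c("z", "a"), aed = c(0.5, 0.5),
                               source_set = "eq")
  expect_equal(selectConsensus(loci2, rec2, list(eq))$chosen_id, "a.t1")
})

test_that("a sole unsupported candidate is kept but flagged for review", {
  ref <- mkSet(list(r1.t1 = gr(101, 200)), "reference")
  res <- reannotate(list(ref), mkEv(setNames(list(), character(0))))
  d <- res$decisions
  expect_equal(d$chosen_id, "r1.t1")
  expect_equal(d$status, "unsupported")
  expect_true(d$review_flag)
  expect_equal(res$summary$n_flagged_unsupported, 1L)
  expect_equal(res$summary$n_unchanged, 1L)  # kept, albeit unsupported
})

test_that("evidence-only loci synthesize models from the merged evidence", {
  ref <- mkSet(list(r1.t1 = gr(101, 200)), "reference")
  ev <- mkEv(list(e1 = gr(101, 200), lone1 = gr(5000, 5400), lone2 = gr(5300, 5800)))
  loci <- buildLoci(list(ref), ev)
  eo <- detectEvidenceOnlyLoci(loci, ev)
  expect_equal(nrow(eo$decisions), 1L)
  expect_equal(eo$decisions$status, "evidence_only")
  # synthesized model spans the union of the two overlapping alignments
  expect_equal(coveredBases(exonRanges(eo$models)[[1L]]),
               coveredBases(gr(c(5000, 5300), c(5400, 5800))))
  # model equals its own evidence footprint -> AED 0
  expect_equal(eo$decisions$chosen_aed, 0)
  # loci holding a model are excluded
  expect_false(any(eo$decisions$locus_id %in%
                     locusMembership(loci)$locus[
                       locusMembership(loci)$kind == "transcript"]))
})

test_that("book-ended evidence segments stay separate exons in synthesized models", {
  ev <- mkEv(list(e1 = gr(c(1, 101), c(100, 200))))
  loci <- buildLoci(list(mkSet(setNames(list(), character(0)), "empty")), ev)
  eo <- detectEvidenceOnlyLoci(loci, ev)
  expect_equal(length(exonRanges(eo$models)[[1L]]), 2L)
})

test_that("bookkeeping conserves reference models and recovers planted truth", {
  fx <- simulateFixture(fixtureSpec(seed = 19, nGenes = 60, nAnnotationSets = 2))
  res <- reannotate(list(fx$reference, fx$alternate), fx$evidence)
  s <- res$summary
  expect_equal(s$n_altered + s$n_unchanged, s$n_input_reference)
  expect_equal(s, fx$truth$summary)

  # worked micro-example: replaced + kept + evidence-only
  ref <- mkSet(list(r1.t1 = gr(101, 300), r2.t1 = gr(1001, 1100)), "reference")
  alt <- mkSet(list(a1.t1 = gr(101, 200)), "alternate")
  ev <- mkEv(list(e1 = gr(101, 200), e2 = gr(1001, 1100), e3 = gr(5000, 5200)))
  res2 <- reannotate(list(ref, alt), ev)
  expect_equal(res2$summary,
               data.frame(n_input_reference = 2L, n_altered = 1L, n_new_loci = 1L,
                          n_unchanged = 1L, n_flagged_unsupported = 0L))
})

test_that("consensus output is non-redundant and a fixed point of re-running", {
  fx <- simulateFixture(fixtureSpec(seed = 23, nGenes = 40, nAnnotationSets = 2))
  res <- reannotate(list(fx$reference, fx$alternate), fx$evidence)

  # chosen models come from distinct loci: no two overlap
  cl <- clusterSingleLinkage(exonRanges(res$consensus))
  expect_equal(length(unique(cl)), length(res$consensus))

  # re-running consensus on its own output changes nothing
  res2 <- reannotate(list(res$consensus), fx$evidence)
  expect_equal(sort(transcriptIds(res2$consensus)),
               sort(transcriptIds(res$consensus)))
  expect_equal(res2$summary$n_altered, 0L)
  expect_equal(res2$summary$n_new_loci, 0L)
})

test_that("review prioritization sorts worst-first with stable ties", {
  rec <- S4Vectors::DataFrame(transcript_id = c("a", "b", "c", "d"),
                              gene_id = c("a", "b", "c", "d"),
                              aed = c(0.1, 1.0, 0.5, 0.5))
  pr <- prioritizeForReview(rec, threshold = 0.95)
  expect_equal(pr$transcript_id, c("b", "c", "d", "a"))
  expect_equal(pr$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(prioritizeForReview(rec, threshold = 0.4)$flagged), 3L)
  # all-zero AEDs flag nothing at the default threshold
  zero <- S4Vectors::DataFrame(transcript_id = "x", gene_id = "x", aed = 0)
  expect_false(any(prioritizeForReview(zero)$flagged))
})
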