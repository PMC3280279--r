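# GFF3 parsing and writing of gene hierarchies and evidence alignments.

writeGff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("a minimal gene/mRNA/exon hierarchy parses", {
  f <- writeGff(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1"))
  set <- readAnnotations(f, "mini")
  expect_s4_class(set, "AnnotationSet")
  expect_equal(length(set), 1L)
  expect_equal(transcriptIds(set), "t1")
  expect_equal(geneIds(set), "g1")
  expect_equal(coveredBases(exonRanges(set)[["t1"]]), 100L)
})

test_that("multi-exon transcripts give position-enumerated covered bases", {
  f <- writeGff(c(
    "chr1\tsrc\tgene\t1\t150\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t150\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t50\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=t1"))
  set <- readAnnotations(f)
  expect_equal(coveredBases(exonRanges(set)[["t1"]]), 100L)
  expect_equal(coveredBases(exonRanges(set)[["t1"]]),
               length(posSet(c(1, 101), c(50, 150))))
})

test_that("parse contract violations are rejected", {
  # exon with absent Parent
  f <- writeGff(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=tMISSING"))
  expect_error(readAnnotations(f), "tMISSING")
  # mRNA with zero exons
  f2 <- writeGff(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1"))
  expect_error(readAnnotations(f2), "zero exons")
})

test_that("dialect tolerance: transcript synonyms, implicit transcripts, skipped types", {
  f <- writeGff(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=g2",
    "chr1\tsrc\texon\t201\t300\t.\t-\t.\tParent=g2",
    "chr1\tsrc\tfive_prime_UTR\t1\t10\t.\t+\t.\tParent=t1"))
  expect_message(set <- readAnnotations(f), "ignored 1 feature")
  expect_setequal(transcriptIds(set), c("t1", "g2.t1"))
  expect_equal(geneIds(set)[transcriptIds(set) == "g2.t1"], "g2")
})

test_that("CDS rows are attached and must stay inside exons", {
  f <- writeGff(c(
    "chr1\tsrc\tgene\t1\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t80\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t121\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t30\t80\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tCDS\t121\t180\t.\t+\t0\tParent=t1"))
  set <- readAnnotations(f)
  expect_equal(coveredBases(cdsRanges(set)[["t1"]]), 51L + 60L)

  fbad <- writeGff(c(
    "chr1\tsrc\tgene\t1\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t80\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t30\t100\t.\t+\t0\tParent=t1"))
  expect_error(readAnnotations(fbad), "outside its exons")
})

test_that("evidence match/match_part hierarchies parse with caller-supplied class", {
  f <- writeGff(c(
    "chr1\tsrc\texpressed_sequence_match\t1\t150\t.\t+\t.\tID=m1",
    "chr1\tsrc\tmatch_part\t1\t50\t.\t+\t.\tParent=m1",
    "chr1\tsrc\tmatch_part\t101\t150\t.\t+\t.\tParent=m1",
    "chr1\tsrc\tmatch\t300\t400\t.\t+\t.\tID=m2"))
  ev <- readEvidence(f, "EST")
  expect_equal(length(ev), 2L)
  expect_equal(coveredBases(partRanges(ev)[["m1"]]), 100L)
  # match with no parts becomes a single-part alignment over its span
  expect_equal(coveredBases(partRanges(ev)[["m2"]]), 101L)
  expect_equal(unname(evidenceClass(ev)), rep("EST", 2))

  # bare rows grouped by shared ID form one alignment
  f2 <- writeGff(c(
    "chr1\tsrc\tmatch\t1\t50\t.\t+\t.\tID=m1",
    "chr1\tsrc\tmatch\t101\t150\t.\t+\t.\tID=m1"))
  ev2 <- readEvidence(f2, "protein")
  expect_equal(length(ev2), 1L)
  expect_equal(coveredBases(partRanges(ev2)[["m1"]]), 100L)

  # empty file -> empty collection
  ev3 <- readEvidence(writeGff(character(0)), "EST")
  expect_equal(length(ev3), 0L)

  # dangling match_part Parent
  f4 <- writeGff("chr1\tsrc\tmatch_part\t1\t50\t.\t+\t.\tParent=ghost")
  expect_error(readEvidence(f4, "EST"), "ghost")
})

test_that("written GFF3 carries formatted _AED attributes on mRNA rows", {
  set <- mkSet(list(t1 = gr(101, 200)), geneId = "g1")
  rec <- S4Vectors::DataFrame(transcript_id = "t1", aed = 0.5417)
  out <- tempfile(fileext = ".gff3")
  writeAnnotations(set, out, aedRecords = rec)
  lines <- readLines(out)
  mrna <- grep("\tmRNA\t", lines, value = TRUE)
  expect_match(mrna, "_AED=0.54", fixed = TRUE)
  zero <- S4Vectors::DataFrame(transcript_id = "t1", aed = 0)
  writeAnnotations(set, out, aedRecords = zero)
  expect_match(grep("\tmRNA\t", readLines(out), value = TRUE),
               "_AED=0.00", fixed = TRUE)
})

test_that("read-write-read round trip preserves ids, coordinates, hierarchy and _AED", {
  set.seed(77)
  fx <- simulateFixture(fixtureSpec(seed = 11, nGenes = 25))
  rec <- computeAEDSet(fx$reference, fx$evidence)
  f1 <- tempfile(fileext = ".gff3")
  writeAnnotations(fx$reference, f1, aedRecords = rec)
  back <- readAnnotations(f1, "reference")

  expect_setequal(transcriptIds(back), transcriptIds(fx$reference))
  ids <- transcriptIds(fx$reference)
  expect_equal(geneIds(back)[match(ids, transcriptIds(back))], geneIds(fx$reference))
  for (id in ids) {
    expect_equal(as.data.frame(granges(exonRanges(back)[[id]])),
                 as.data.frame(granges(exonRanges(fx$reference)[[id]])),
                 info = id)
  }
  # _AED survives the round trip at 2-decimal precision
  aed_back <- as.numeric(txData(back)$`_AED`)[match(ids, transcriptIds(back))]
  expect_equal(aed_back, round(rec$aed, 2), tolerance = 1e-9)

  # a second write from the re-read object is byte-stable on feature rows
  f2 <- tempfile(fileext = ".gff3")
  writeAnnotations(back, f2, aedRecords = rec)
  strip <- function(f) grep("^[^#]", readLines(f), value = TRUE)
  expect_identical(strip(f2), strip(f1))
})
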