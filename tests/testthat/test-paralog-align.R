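test_that("identical sequences align without gaps and with full identity", {
  aln <- alignParalogs("ACGTACGTAC", "ACGTACGTAC")
  st <- identityVector(aln)
  expect_equal(unname(st["alignedLength"]), 10L)
  expect_equal(unname(st["identical"]), 10L)
  expect_equal(unname(st["gapColumns"]), 0L)
  expect_length(enumeratePsvs(aln), 0L)
})

test_that("the single-deletion pair aligns as derived by the DP oracle", {
  aln <- alignParalogs("ACGTACGT", "ACGACGT")
  expect_equal(geneAligned(aln), "ACGTACGT")
  expect_equal(pseudoAligned(aln), "ACG-ACGT")
  expect_equal(alignmentScore(aln), gotohScore("ACGTACGT", "ACGACGT"))
  st <- identityVector(aln)
  expect_equal(unname(st[c("alignedLength", "identical", "mismatches",
                           "gapColumns", "gapRuns")]),
               c(8L, 7L, 0L, 1L, 1L))
})

test_that("all-mismatch alignments are tallied as mismatches", {
  st <- identityVector(alignParalogs("AAAA", "TTTT"))
  expect_equal(unname(st[c("alignedLength", "identical", "mismatches",
                           "gapColumns", "gapRuns")]),
               c(4L, 0L, 4L, 0L, 0L))
})

test_that("input validation rejects empty and non-nucleotide sequences", {
  expect_error(alignParalogs("", "ACGT"), "non-empty")
  expect_error(alignParalogs("ACGT", "ACXT"), "non-nucleotide")
})

test_that("N bases never count as identical and N-only runs define no PSV", {
  aln <- alignParalogs("ACNTA", "ACNTA")
  st <- identityVector(aln)
  expect_equal(unname(st["identical"]), 4L)
  expect_equal(unname(st["mismatches"]), 1L)
  expect_length(enumeratePsvs(aln), 0L)
  ## N adjacent to a real difference flags the PSV as ambiguous
  aln2 <- alignParalogs("ACGNTA", "ACTNTA")
  psv <- enumeratePsvs(aln2)
  expect_length(psv, 1L)
  expect_true(all(S4Vectors::mcols(psv)$ambiguous))
})

test_that("alignment score matches the exhaustive DP oracle on short pairs", {
  withr::with_seed(11, {
    for (i in 1:60) {
      x <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE),
                 collapse = "")
      y <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE),
                 collapse = "")
      expect_equal(alignmentScore(alignParalogs(x, y)), gotohScore(x, y),
                   info = paste(x, y))
    }
  })
})

test_that("column tallies always partition the alignment length", {
  for (seed in 1:10) {
    sim <- simulateParalogPair(400L, nSubs = 6L, nIndels = 2L,
                               maxIndel = 2L, seed = seed)
    st <- identityVector(alignParalogs(sim$geneSeq, sim$pseudoSeq))
    expect_equal(unname(st["identical"] + st["mismatches"] + st["gapColumns"]),
                 unname(st["alignedLength"]))
  }
})

test_that("deletions are reported at their 3'-most equivalent position", {
  gene <- "ACGGGTAACGT"
  pseudo <- "ACGGTAACGT"  # one G of the run removed
  aln <- alignParalogs(gene, pseudo,
                       geneOrigin = GenomicRanges::GRanges(
                         "g", IRanges::IRanges(101, 111)))
  psv <- enumeratePsvs(aln)
  expect_length(psv, 1L)
  expect_equal(S4Vectors::mcols(psv)$kind, "deletion")
  expect_equal(start(psv), 100L + bruteDeletion3Prime(gene, pseudo))
  expect_equal(S4Vectors::mcols(psv)$label, "g.105del")
})

test_that("insertions in the pseudogene are anchored and labelled in HGVS style", {
  ## pseudogene has an extra base after gene position 4
  aln <- alignParalogs("ACGTCCGTA", "ACGTACCGTA",
                       geneOrigin = GenomicRanges::GRanges(
                         "g", IRanges::IRanges(201, 209)))
  psv <- enumeratePsvs(aln)
  expect_length(psv, 1L)
  expect_equal(S4Vectors::mcols(psv)$kind, "insertion")
  expect_equal(S4Vectors::mcols(psv)$geneAllele, "")
  expect_match(S4Vectors::mcols(psv)$label, "^g\\.[0-9]+_[0-9]+insA$")
})

test_that("psvsInInterval uses inclusive endpoints and checks the contig", {
  psvs <- exon7Psvs()
  amp <- exon7Amplicon()
  expect_length(psvsInInterval(psvs, amp), 5L)
  point <- GenomicRanges::GRanges("chr15", IRanges::IRanges(45069023, 45069023))
  expect_equal(S4Vectors::mcols(psvsInInterval(psvs, point))$label,
               "g.45069023del")
  far <- GenomicRanges::GRanges("chr15", IRanges::IRanges(1, 100))
  expect_length(psvsInInterval(psvs, far), 0L)
  wrong <- GenomicRanges::GRanges("chr2", IRanges::IRanges(45068800, 45069200))
  expect_error(psvsInInterval(psvs, wrong), "contig")
})

test_that("cDNA-to-genomic mapping walks the exon structure correctly", {
  one <- transcriptModel("chr1", "+", IRanges::IRanges(101, 150))
  expect_equal(mapCoordinates(one, 1), 101L)
  two <- transcriptModel("chr1", "+", IRanges::IRanges(c(101, 201), c(150, 260)))
  expect_equal(mapCoordinates(two, 60), 210L)
  expect_error(mapCoordinates(two, 1000), "range error")
  expect_error(mapGenomic(two, 180), "not-exonic")
  ## minus strand counts in transcript orientation
  minus <- transcriptModel("chr1", "-", IRanges::IRanges(c(101, 201), c(150, 260)))
  expect_equal(mapCoordinates(minus, 1), 260L)
  expect_equal(mapCoordinates(minus, 61), 150L)
})

test_that("coordinate mapping round-trips on every coding position", {
  models <- list(
    transcriptModel("c", "+", IRanges::IRanges(c(11, 61, 121), c(40, 90, 180)),
                    cdsStartOffset = 7L),
    transcriptModel("c", "-", IRanges::IRanges(c(11, 61, 121), c(40, 90, 180)),
                    cdsStartOffset = 12L))
  for (m in models) {
    codingLen <- sum(IRanges::width(m@exons)) - m@cdsStartOffset
    cPos <- seq_len(codingLen)
    g <- mapCoordinates(m, cPos)
    expect_equal(mapGenomic(m, g), cPos)
  }
})

test_that("alignment dump writes the two gapped rows verbatim", {
  aln <- alignParalogs("ACGTACGT", "ACGACGT")
  f <- withr::local_tempfile(fileext = ".txt")
  writeAlignment(aln, f)
  expect_equal(readLines(f), c("ACGTACGT", "ACG-ACGT"))
})
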