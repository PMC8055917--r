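test_that("percent-formatted TSV frequencies are parsed as fractions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#contig\tpos\tchange\tfrequency",
               "chr15\t45069181\tA>C\t21.94%"), f)
  ft <- loadFrequencyTable(f, "tsv")
  expect_equal(length(ft), 1L)
  v <- variants(ft)
  expect_equal(S4Vectors::mcols(v)$frequency, 0.2194)
  expect_equal(S4Vectors::mcols(v)$ref, "A")
  expect_equal(S4Vectors::mcols(v)$alt, "C")
})

test_that("an empty table file loads as an empty table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#contig\tpos\tchange\tfrequency", f)
  expect_equal(length(loadFrequencyTable(f, "tsv")), 0L)
})

test_that("TSV frequencies outside [0,1] and malformed rows are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\tA>C\t150%", f)
  expect_error(loadFrequencyTable(f, "tsv"), "value error")
  writeLines("chr1\t100\tA-C\t0.2", f)
  expect_error(loadFrequencyTable(f, "tsv"), "format error")
})

writeTestVcf <- function(lines) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele Count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele Number\">",
    "##contig=<ID=chr15>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines), f)
  f
}

test_that("VCF loading honours AF, falls back to AC/AN, splits multi-allelics", {
  f <- writeTestVcf(c(
    "chr15\t45069181\t.\tA\tC\t.\t.\tAF=0.2194",
    "chr15\t45068982\t.\tA\tT\t.\t.\tAC=177;AN=1000",
    "chr15\t45069043\t.\tG\tA,T\t.\t.\tAF=0.0177,0.001"))
  ft <- loadFrequencyTable(f, "vcf")
  expect_equal(length(ft), 4L)
  v <- variants(ft)
  expect_equal(sort(S4Vectors::mcols(v)$frequency),
               sort(c(0.2194, 0.177, 0.0177, 0.001)))
  byAlt <- S4Vectors::mcols(v)$frequency[S4Vectors::mcols(v)$alt == "T" &
                                           start(v) == 45069043]
  expect_equal(byAlt, 0.001)
})

test_that("a VCF with neither AF nor AC/AN is a format error", {
  f <- writeTestVcf("chr15\t100\t.\tA\tC\t.\t.\t.")
  expect_error(loadFrequencyTable(f, "vcf"), "format error")
})

test_that("frequency tables round-trip through TSV exactly", {
  ft <- frequencyTable("chr15", c(101L, 202L, 303L),
                       c("A", "G", "TA"), c("C", "A", "T"),
                       c(0.2194, 0.0177, 1 / 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFrequencyTable(ft, f)
  back <- loadFrequencyTable(f, "tsv")
  expect_equal(S4Vectors::mcols(variants(back))$frequency,
               S4Vectors::mcols(variants(ft))$frequency, tolerance = 1e-9)
  expect_equal(start(variants(back)), start(variants(ft)))
})

test_that("footprint queries use a strict frequency threshold", {
  ft <- exon7Frequencies()
  fp <- GenomicRanges::GRanges("chr15", IRanges::IRanges(45069170, 45069194))
  hit <- frequentVariantsInFootprint(ft, fp, 0.01)
  expect_equal(length(hit), 1L)
  expect_equal(S4Vectors::mcols(hit)$frequency, 0.2194)
  ## below-threshold and at-threshold variants are not returned
  low <- frequencyTable("chr15", 45069180L, "A", "G", 0.005)
  expect_length(frequentVariantsInFootprint(low, fp, 0.01), 0L)
  at <- frequencyTable("chr15", 45069180L, "A", "G", 0.01)
  expect_length(frequentVariantsInFootprint(at, fp, 0.01), 0L)
  ## threshold 0 returns every overlapping variant, threshold 1 none
  expect_length(frequentVariantsInFootprint(ft, fp, 0), 1L)
  full <- GenomicRanges::GRanges("chr15", IRanges::IRanges(1, 5e7))
  expect_length(frequentVariantsInFootprint(ft, full, 0), 3L)
  expect_length(frequentVariantsInFootprint(ft, full, 1), 0L)
})

test_that("PSV frequency annotation requires allele identity, not just position", {
  ann <- annotatePsvFrequencies(exon7Psvs(), exon7Frequencies())
  freqByLabel <- stats::setNames(S4Vectors::mcols(ann)$frequency,
                                 S4Vectors::mcols(ann)$label)
  expect_equal(unname(freqByLabel["g.45068982A>T"]), 0.257)
  expect_equal(unname(freqByLabel["g.45069043G>A"]), 0.0177)
  expect_equal(unname(freqByLabel["g.45069087A>G"]), 0)
  expect_equal(unname(freqByLabel["g.45068867_45068868del"]), 0)
  ## same position, different alt allele: no match
  other <- frequencyTable("chr15", 45068982L, "A", "G", 0.5)
  ann2 <- annotatePsvFrequencies(exon7Psvs(), other)
  expect_equal(sum(S4Vectors::mcols(ann2)$frequency), 0)
})

test_that("indel PSVs match VCF-anchored population representations", {
  ## deletion of CT at 301-302, table stores anchored ref=ACT alt=A at 300
  psv <- psvRanges("chr1", 301L, 302L, "deletion", "CT", "")
  ft <- frequencyTable("chr1", 300L, "ACT", "A", 0.12)
  ann <- annotatePsvFrequencies(psv, ft)
  expect_equal(S4Vectors::mcols(ann)$frequency, 0.12)
})

test_that("Grantham distances reproduce the published scale", {
  expect_equal(granthamDistance("Ser", "Leu"), 145)
  expect_equal(granthamDistance("Gly", "Asp"), 94)
  expect_equal(granthamDistance("Gly", "Arg"), 125)
  expect_equal(granthamDistance("Ala", "Ala"), 0)
  m <- granthamMatrix()
  expect_equal(max(m), 215)
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
  ## one- and three-letter codes are interchangeable
  expect_equal(granthamDistance("S", "L"), granthamDistance("Ser", "Leu"))
  expect_error(granthamDistance("Xyz", "Ala"), "input error")
})
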