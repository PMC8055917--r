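looseConstraints <- function(...) {
  primerConstraints(lengthRange = c(18L, 24L), gcRange = c(0, 1),
                    tmRange = c(20, 95), ...)
}

test_that("Wallace-rule melting temperatures follow 2(A+T) + 4(G+C)", {
  expect_equal(meltingTemperature("ACGTACGTACGTACGTACGT", "wallace"), 60)
  expect_equal(meltingTemperature("AAAAAAAAAA", "wallace"), 20)
  expect_equal(meltingTemperature("GCGCGCGC", "wallace"), 32)
  ## adding one G raises the Wallace Tm by exactly 4
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      expect_equal(meltingTemperature(paste0(s, "G"), "wallace"),
                   meltingTemperature(s, "wallace") + 4)
    }
  })
})

test_that("nearest-neighbor Tm is deterministic and rejects bad input", {
  s <- "GCTCACGCAGCAAGCTGGTAAAG"
  expect_equal(meltingTemperature(s), meltingTemperature(s))
  expect_gt(meltingTemperature(s), 50)
  expect_lt(meltingTemperature(s), 75)
  ## GC-richer sequences melt higher
  expect_gt(meltingTemperature("GCGCGCGCGCGCGCGCGCGC"),
            meltingTemperature("ATATATATATATATATATAT"))
  expect_error(meltingTemperature("ACGTACGTRACGTACG"), "non-nucleotide")
  expect_error(meltingTemperature("ACGT"), "at least 8")
})

test_that("specificity scoring measures PSV offsets from the primer 3' end", {
  psvs <- psvRanges("g", c(120L, 150L), c(120L, 150L), "substitution",
                    "A", "G")
  ## forward primer ending exactly on the PSV at 120
  fwd <- primer("ACGTACGTACGTACGTACGT", 101L, "forward", "g")
  rep1 <- specificityScore(fwd, psvs)
  expect_true(rep1@isSpecific)
  expect_equal(rep1@psvOffsets, 0L)
  ## PSV 10 bases in from the 3' end is outside the default window
  fwd2 <- primer("ACGTACGTACGTACGTACGT", 111L, "forward", "g")
  rep2 <- specificityScore(fwd2, psvs)
  expect_false(rep2@isSpecific)
  expect_equal(rep2@psvOffsets, 10L)
  expect_true(specificityScore(fwd2, psvs, window = 11L)@isSpecific)
  ## no PSV under the footprint
  far <- primer("ACGTACGTACGTACGTACGT", 500L, "forward", "g")
  rep3 <- specificityScore(far, psvs)
  expect_false(rep3@isSpecific)
  expect_length(rep3@psvOffsets, 0L)
  expect_equal(rep3@min3PrimeOffset, Inf)
  ## reverse primers count offsets from their (left-edge) 3' end
  rev <- primer("ACGTACGTACGTACGTACGT", 150L, "reverse", "g")
  expect_equal(specificityScore(rev, psvs)@psvOffsets, 0L)
})

test_that("SNP collision uses the strict >threshold dropout rule", {
  prm <- primer("ACGTACGTACGTACGTACGTACG", 45069170L, "forward", "chr15")
  hit <- checkSnpCollision(prm, exon7Frequencies())
  expect_true(hit$dropoutRisk)
  expect_equal(S4Vectors::mcols(hit$collidingSnps)$frequency, 0.2194)
  clean <- checkSnpCollision(prm, frequencyTable())
  expect_false(clean$dropoutRisk)
  atThreshold <- frequencyTable("chr15", 45069181L, "A", "C", 0.01)
  expect_false(checkSnpCollision(prm, atThreshold, 0.01)$dropoutRisk)
})

test_that("every candidate places the lone PSV in its 3' window", {
  withr::with_seed(5, {
    gene <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  })
  psvs <- psvRanges("gene", 40L, 40L, "substitution",
                    substr(gene, 40, 40),
                    setdiff(c("A", "C", "G", "T"), substr(gene, 40, 40))[1])
  region <- GenomicRanges::GRanges("gene", IRanges::IRanges(1, 60))
  cands <- generatePrimerCandidates(gene, region, psvs, frequencyTable(),
                                    looseConstraints())
  expect_gt(length(cands), 0L)
  for (prm in cands) {
    rep <- specificityScore(prm, psvs)
    expect_true(rep@isSpecific)
    expect_lt(rep@min3PrimeOffset, 3)
  }
})

test_that("candidate generation fails with machine-readable reasons", {
  withr::with_seed(6, {
    gene <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  })
  region <- GenomicRanges::GRanges("gene", IRanges::IRanges(1, 60))
  noPsv <- psvRanges("gene", integer(0), integer(0), character(0),
                     character(0), character(0))
  res <- generatePrimerCandidates(gene, region, noPsv, frequencyTable(),
                                  looseConstraints())
  expect_length(res, 0L)
  expect_equal(attr(res, "failure")$stage, "no paralog-discriminating site")
  ## the only PSV co-locates with a 5% SNP: both filters leave nothing
  ref40 <- substr(gene, 40, 40)
  alt40 <- setdiff(c("A", "C", "G", "T"), ref40)[1]
  psvs <- psvRanges("gene", 40L, 40L, "substitution", ref40, alt40)
  snp <- frequencyTable("gene", 40L, ref40, alt40, 0.05)
  res2 <- generatePrimerCandidates(gene, region, psvs, snp,
                                   looseConstraints())
  expect_length(res2, 0L)
  expect_equal(attr(res2, "failure")$stage, "snp_collision")
})

test_that("in-silico PCR predicts co-amplification and 3'-mismatch rescue", {
  fwdSite <- "ACGTTGCAGCTAGGCTAA"
  revSite <- "TTCGGATCCATGGCAATC"   # bottom-strand primer binding site
  spacer <- strrep("ATGGC", 10)
  gene <- paste0("GG", fwdSite, spacer, revSite, "CC")
  fwd <- fwdSite
  rev <- bruteRevComp(revSite)
  ## identical site on both templates: product on both (co-amplification)
  pseudo <- paste0("TT", fwdSite, spacer, revSite, "AA")
  expect_equal(nrow(inSilicoPcr(fwd, rev, gene)), 1L)
  expect_equal(nrow(inSilicoPcr(fwd, rev, pseudo)), 1L)
  ## a 3'-terminal mismatch on the pseudogene blocks binding there
  fwdSiteMut <- paste0(substr(fwdSite, 1, 17),
                       setdiff(c("A", "C", "G", "T"),
                               substr(fwdSite, 18, 18))[1])
  pseudoMut <- paste0("TT", fwdSiteMut, spacer, revSite, "AA")
  expect_equal(nrow(inSilicoPcr(fwd, rev, gene)), 1L)
  expect_equal(nrow(inSilicoPcr(fwd, rev, pseudoMut)), 0L)
  ## divergent orientation yields no product
  divergent <- paste0("GG", bruteRevComp(fwdSite), spacer, revSite, "CC")
  expect_equal(nrow(inSilicoPcr(fwd, rev, divergent)), 0L)
  ## the length cap suppresses distant pairings
  expect_equal(nrow(inSilicoPcr(fwd, rev, gene, bindingModel(maxProduct = 30))),
               0L)
})

test_that("in-silico PCR equals the exhaustive scan on short templates", {
  withr::with_seed(17, {
    for (i in 1:20) {
      template <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = "")
      s1 <- sample(1:80, 1)
      s2 <- sample(120:180, 1)
      fwd <- substr(template, s1, s1 + 15)
      rev <- bruteRevComp(substr(template, s2, s2 + 15))
      ## perturb one internal base of the forward primer half the time
      if (i %% 2 == 0) {
        pos <- sample(2:10, 1)
        substr(fwd, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                         substr(fwd, pos, pos))[1]
      }
      got <- inSilicoPcr(fwd, rev, template)
      want <- brutePcrProducts(fwd, rev, template)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  })
})

test_that("designAssay yields a gene-only amplicon with clean primers", {
  fix <- designFixture(seed = 101)
  assay <- designAssay(fix$geneSeq, fix$pseudoSeq, fix$region,
                       config = assayConfig(constraints = looseConstraints()))
  expect_s4_class(assay, "AmpliconAssay")
  prm <- assayPrimers(assay)
  expect_equal(nrow(inSilicoPcr(prm$forward, prm$reverse, fix$geneSeq)), 1L)
  expect_equal(nrow(inSilicoPcr(prm$forward, prm$reverse, fix$pseudoSeq)), 0L)
  expect_true(assay@reports$forward@isSpecific)
  expect_true(assay@reports$reverse@isSpecific)
  amp <- assayAmplicon(assay)
  expect_lte(start(amp), 300L)
  expect_gte(end(amp), 400L)
})

test_that("identical gene and pseudogene is an infeasible design", {
  withr::with_seed(9, {
    gene <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  })
  region <- GenomicRanges::GRanges("gene", IRanges::IRanges(200, 300))
  err <- tryCatch(
    designAssay(gene, gene, region,
                config = assayConfig(constraints = looseConstraints())),
    psvkitDesignError = function(e) e)
  expect_s3_class(err, "psvkitDesignError")
  expect_equal(err$stage, "no paralog-discriminating site")
})

test_that("the sequencing primer avoids a frequent SNP inside the amplicon", {
  ## PSV flanks far enough out that a sequencing-primer window exists
  pos <- c(150L, 180L, 210L, 240L, 420L, 450L, 480L, 510L, 100L, 600L)
  sim <- simulateParalogPair(length = 700L, nSubs = 10L, nIndels = 0L,
                             seed = 33, positions = pos)
  region <- GenomicRanges::GRanges("gene", IRanges::IRanges(300, 400))
  snpPos <- 270L
  snp <- frequencyTable("gene", snpPos, substr(sim$geneSeq, snpPos, snpPos),
                        setdiff(c("A", "C", "G", "T"),
                                substr(sim$geneSeq, snpPos, snpPos))[1],
                        0.2194)
  assay <- designAssay(sim$geneSeq, sim$pseudoSeq, region, table = snp,
                       config = assayConfig(constraints = looseConstraints(),
                                            maxFlank = 180L))
  sp <- assay@sequencingPrimer
  expect_false(is.null(sp))
  fp <- primerFootprint(sp)
  expect_true(snpPos < start(fp) || snpPos > end(fp))
  ## no designed primer footprint overlaps a frequent SNP (post-hoc check)
  for (p in assayPrimers(assay))
    expect_false(checkSnpCollision(p, snp)$dropoutRisk)
})

test_that("assay reports serialize to primer TSV and JSON", {
  fix <- designFixture(seed = 101)
  assay <- designAssay(fix$geneSeq, fix$pseudoSeq, fix$region,
                       config = assayConfig(constraints = looseConstraints()))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePrimerTsv(assay, tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_true(all(c("forward", "reverse") %in% df$role))
  expect_true(all(df$specific[df$role %in% c("forward", "reverse")]))
  js <- withr::local_tempfile(fileext = ".json")
  writeAssayJson(assay, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$forward$sequence, primerSequence(assay@forward))
  expect_equal(parsed$panel$k, 3L)
})
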