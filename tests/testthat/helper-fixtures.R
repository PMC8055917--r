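## Shared fixtures: the exon-7-style amplicon geometry (five gene/pseudogene
## differences, two of them polymorphic within the gene) and the published
## cohort tallies, all built in code.

exon7Psvs <- function() {
  psvRanges(
    contig = "chr15",
    start = c(45068867L, 45068982L, 45069023L, 45069043L, 45069087L),
    end   = c(45068868L, 45068982L, 45069023L, 45069043L, 45069087L),
    kind = c("deletion", "substitution", "deletion", "substitution",
             "substitution"),
    geneAllele = c("TG", "A", "C", "G", "A"),
    pseudoAllele = c("", "T", "", "A", "G"))
}

## Gene-internal population frequencies: two of the PSV sites are
## themselves polymorphic in the gene (25.7% and 1.77%), plus the frequent
## SNP (21.94%) under the originally published sequencing primer.
exon7Frequencies <- function() {
  frequencyTable(
    contig = "chr15",
    pos = c(45068982L, 45069043L, 45069181L),
    ref = c("A", "G", "A"),
    alt = c("T", "A", "C"),
    frequency = c(0.257, 0.0177, 0.2194),
    source = "gnomAD")
}

exon7TargetLabel <- function() "g.45069023del"

exon7Amplicon <- function() {
  GenomicRanges::GRanges("chr15", IRanges::IRanges(45068800L, 45069200L))
}

## Published cohort roster: 9 homozygotes for the frameshift deletion,
## 9 compound heterozygotes (6 + 1 + 1 + 1), 6 single-variant carriers.
cohortRoster <- function() {
  second <- c(rep("c.458C>A", 6L), "c.218C>T", "c.503G>A", "c.553G>A")
  data.frame(
    patient = sprintf("P%02d", 1:24),
    family = sprintf("F%02d", 1:24),
    allele1 = rep("c.757del", 24L),
    allele2 = c(rep("c.757del", 9L), second, rep(NA_character_, 6L)),
    stringsAsFactors = FALSE)
}

## Screening-cascade tallies: fragment analysis of 931 (17 positive, 11 of
## them biallelic), the 387-patient axonal subgroup, the 58-exome arm, and
## the whole solved-HN registry.
cohortCascade <- function() {
  data.frame(
    arm = c("fragment_analysis", "axonal_subgroup", "wes_reanalysis",
            "all_diagnosed", "fragment_biallelic"),
    nTested = c(931L, 387L, 58L, 2313L, 931L),
    nPositive = c(17L, 17L, 3L, 18L, 11L),
    stringsAsFactors = FALSE)
}

## A design scenario with substitutions planted in both primer flanks.
designFixture <- function(seed, length = 700L, regionStart = 300L,
                          regionEnd = 400L) {
  pos <- c(190L, 220L, 255L, 285L, 420L, 450L, 480L, 510L, 120L, 600L)
  sim <- simulateParalogPair(length = length, nSubs = 10L, nIndels = 0L,
                             seed = seed, positions = pos)
  sim$region <- GenomicRanges::GRanges(
    "gene", IRanges::IRanges(regionStart, regionEnd))
  sim
}
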