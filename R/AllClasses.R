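## Central S4 containers.  Genomic intervals are plain GRanges (1-based,
## inclusive, the HGVS "g." frame); PSVs and population variants are GRanges
## with documented metadata columns rather than bespoke classes, in the
## style of VariantAnnotation.

#' TranscriptModel: exon structure for c. <-> g. coordinate mapping
#'
#' Holds the ordered exons of one transcript plus the offset of the first
#' coding base, enough to translate cDNA (c.) positions into genomic (g.)
#' positions and back.
#'
#' @slot contig Chromosome / contig name.
#' @slot strand `"+"` or `"-"`; cDNA positions always count in transcript
#'   orientation.
#' @slot exons [GenomicRanges::GRanges] of exons stored 5'->3' in transcript
#'   orientation (descending genomic start for minus-strand models).
#' @slot cdsStartOffset Bases into the spliced transcript before c.1
#'   (0 when the transcript starts at the CDS).
#'
#' @seealso [transcriptModel()], [mapCoordinates()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    contig = "character",
    strand = "character",
    exons = "GRanges",
    cdsStartOffset = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@contig) != 1L) msg <- c(msg, "contig must be a single string")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@exons) == 0L) msg <- c(msg, "at least one exon required")
  st <- start(object@exons); en <- end(object@exons)
  if (any(st > en) || any(st < 1L)) msg <- c(msg, "exon start must be positive and <= end")
  o <- order(st)
  if (length(object@exons) > 1L) {
    so <- st[o]; eo <- en[o]
    if (any(so[-1L] <= eo[-length(eo)])) msg <- c(msg, "exons must not overlap")
    expected <- if (object@strand == "+") seq_along(st) else rev(seq_along(st))
    if (!identical(o, expected))
      msg <- c(msg, "exons must be ordered 5'->3' in transcript orientation")
  }
  if (object@cdsStartOffset < 0L) msg <- c(msg, "cdsStartOffset must be >= 0")
  if (sum(width(object@exons)) < object@cdsStartOffset + 1L)
    msg <- c(msg, "spliced length must exceed cdsStartOffset")
  if (length(msg)) msg else TRUE
})

#' ParalogAlignment: gapped global alignment of a gene and its pseudogene
#'
#' @slot geneAligned,pseudoAligned Equal-length gapped strings (`-` for
#'   gaps); removing gaps reproduces the input sequences.
#' @slot score Alignment score under the scoring in `scoring`.
#' @slot geneOrigin Single-range [GenomicRanges::GRanges] giving the genomic
#'   position of the first gene base (plus strand).
#' @slot columnToGenePos Integer vector, one entry per alignment column:
#'   the 1-based gene position of that column; columns that are gaps in the
#'   gene row map to the preceding gene base (0 before the first).
#' @slot scoring The scoring parameters used (see [alignmentScoring()]).
#'
#' @seealso [alignParalogs()], [identityStats()], [enumeratePsvs()]
#' @exportClass ParalogAlignment
setClass("ParalogAlignment",
  representation(
    geneAligned = "character",
    pseudoAligned = "character",
    score = "numeric",
    geneOrigin = "GRanges",
    columnToGenePos = "integer",
    scoring = "list"
  )
)

setValidity("ParalogAlignment", function(object) {
  msg <- character()
  g <- object@geneAligned; p <- object@pseudoAligned
  if (length(g) != 1L || length(p) != 1L) msg <- c(msg, "aligned strings must be single strings")
  else {
    if (nchar(g) != nchar(p)) msg <- c(msg, "aligned strings must have equal length")
    gc <- strsplit(g, "")[[1L]]; pc <- strsplit(p, "")[[1L]]
    if (any(gc == "-" & pc == "-")) msg <- c(msg, "no column may be a gap in both rows")
    if (length(object@columnToGenePos) != nchar(g))
      msg <- c(msg, "columnToGenePos must have one entry per column")
  }
  if (length(object@geneOrigin) != 1L) msg <- c(msg, "geneOrigin must be a single range")
  if (length(msg)) msg else TRUE
})

#' IdentityStats: column-wise tallies of a paralog alignment
#'
#' @slot alignedLength,identical,mismatches,gapColumns Column counts;
#'   `identical + mismatches + gapColumns == alignedLength`.
#' @slot gapRuns Number of maximal runs of contiguous gap columns in one row.
#'
#' @seealso [identityStats()]
#' @exportClass IdentityStats
setClass("IdentityStats",
  representation(
    alignedLength = "integer",
    identical = "integer",
    mismatches = "integer",
    gapColumns = "integer",
    gapRuns = "integer"
  )
)

setValidity("IdentityStats", function(object) {
  msg <- character()
  vals <- c(object@alignedLength, object@identical, object@mismatches,
            object@gapColumns, object@gapRuns)
  if (any(vals < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (object@identical + object@mismatches + object@gapColumns != object@alignedLength)
    msg <- c(msg, "identical + mismatches + gapColumns must equal alignedLength")
  if (length(msg)) msg else TRUE
})

#' FrequencyTable: coordinate-indexed population allele frequencies
#'
#' Thin wrapper around a [GenomicRanges::GRanges] whose metadata columns are
#' `ref`, `alt`, `frequency` (fraction in \[0,1\]) and `source`.
#'
#' @slot variants The variant [GenomicRanges::GRanges].
#'
#' @seealso [frequencyTable()], [loadFrequencyTable()],
#'   [frequentVariantsInFootprint()]
#' @exportClass FrequencyTable
setClass("FrequencyTable", representation(variants = "GRanges"))

setValidity("FrequencyTable", function(object) {
  v <- object@variants
  needed <- c("ref", "alt", "frequency", "source")
  if (!all(needed %in% colnames(mcols(v))))
    return(sprintf("variants must carry metadata columns: %s",
                   paste(needed, collapse = ", ")))
  f <- mcols(v)$frequency
  if (length(f) && (any(is.na(f)) || any(f < 0) || any(f > 1)))
    return("frequency must lie in [0, 1]")
  if (length(v) && any(as.character(mcols(v)$ref) == as.character(mcols(v)$alt)))
    return("ref and alt alleles must differ")
  TRUE
})

#' Primer: one oligonucleotide with its genomic footprint
#'
#' @slot sequence 5'->3' primer sequence; reverse primers are stored as the
#'   reverse complement of the gene top strand.
#' @slot footprint Single-range [GenomicRanges::GRanges] on the gene top
#'   strand covered by the primer.
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot tm Predicted melting temperature (degrees Celsius).
#' @slot gc GC content as a fraction.
#'
#' @seealso [primer()], [specificityScore()], [checkSnpCollision()]
#' @exportClass Primer
setClass("Primer",
  representation(
    sequence = "character",
    footprint = "GRanges",
    orientation = "character",
    tm = "numeric",
    gc = "numeric"
  )
)

setValidity("Primer", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  if (length(object@sequence) != 1L || n < 15L || n > 35L)
    msg <- c(msg, "primer sequence must be a single string of length 15-35")
  if (!grepl("^[ACGT]+$", object@sequence))
    msg <- c(msg, "primer sequence must be over {A,C,G,T}")
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(object@footprint) != 1L)
    msg <- c(msg, "footprint must be a single range")
  else if (width(object@footprint) != n)
    msg <- c(msg, "footprint width must equal primer length")
  gcTrue <- gcFraction(object@sequence)
  if (length(object@gc) != 1L || abs(object@gc - gcTrue) > 1e-6)
    msg <- c(msg, "gc slot must equal the GC fraction of the sequence")
  if (length(msg)) msg else TRUE
})

#' SpecificityReport: how well a primer discriminates gene from pseudogene
#'
#' @slot psvOffsets Offsets (0 = 3'-terminal base) of PSVs under the primer
#'   footprint, counted from the primer 3' end.
#' @slot min3PrimeOffset Smallest offset (`Inf` when no PSV is covered).
#' @slot isSpecific `TRUE` when at least one PSV lies within the 3' window.
#' @slot collidingSnps Population variants above the frequency threshold
#'   under the footprint (allele-dropout risk).
#' @slot dropoutRisk `TRUE` iff `collidingSnps` is non-empty.
#'
#' @seealso [specificityScore()], [checkSnpCollision()]
#' @exportClass SpecificityReport
setClass("SpecificityReport",
  representation(
    psvOffsets = "integer",
    min3PrimeOffset = "numeric",
    isSpecific = "logical",
    collidingSnps = "GRanges",
    dropoutRisk = "logical"
  )
)

setValidity("SpecificityReport", function(object) {
  msg <- character()
  if (object@isSpecific && length(object@psvOffsets) == 0L)
    msg <- c(msg, "a specific primer must cover at least one PSV")
  if (object@dropoutRisk != (length(object@collidingSnps) > 0L))
    msg <- c(msg, "dropoutRisk must mirror non-emptiness of collidingSnps")
  if (length(msg)) msg else TRUE
})

#' DiagnosticPanel: PSV sites used to confirm gene-specific amplification
#'
#' @slot sites PSV [GenomicRanges::GRanges] (metadata columns `label` and
#'   `frequency`), sorted by gene-internal polymorphism frequency then
#'   position.
#' @slot k Requested panel size.
#' @slot warnings Text flags (e.g. a selected site is itself polymorphic in
#'   the gene above the warning threshold).
#' @slot infeasible `TRUE` when fewer than `k` eligible sites existed.
#'
#' @seealso [selectPanel()], [classifyTrace()]
#' @exportClass DiagnosticPanel
setClass("DiagnosticPanel",
  representation(
    sites = "GRanges",
    k = "integer",
    warnings = "character",
    infeasible = "logical"
  )
)

setValidity("DiagnosticPanel", function(object) {
  msg <- character()
  if (!object@infeasible && length(object@sites) != object@k)
    msg <- c(msg, "a feasible panel must contain exactly k sites")
  if (!all(c("label", "frequency") %in% colnames(mcols(object@sites))))
    msg <- c(msg, "sites must carry 'label' and 'frequency' metadata columns")
  if (length(msg)) msg else TRUE
})

setClassUnion("PrimerOrNULL", c("Primer", "NULL"))

#' AmpliconAssay: a fully specified gene-specific PCR/sequencing assay
#'
#' @slot forward,reverse The PCR [Primer] pair.
#' @slot sequencingPrimer Optional internal sequencing [Primer].
#' @slot amplicon Genomic span from the forward primer start to the reverse
#'   primer end.
#' @slot psvs PSVs inside the amplicon (gene/pseudogene differences).
#' @slot panel [DiagnosticPanel] attached to the assay.
#' @slot reports Per-primer [SpecificityReport] objects (named list).
#'
#' @seealso [designAssay()]
#' @exportClass AmpliconAssay
setClass("AmpliconAssay",
  representation(
    forward = "Primer",
    reverse = "Primer",
    sequencingPrimer = "PrimerOrNULL",
    amplicon = "GRanges",
    psvs = "GRanges",
    panel = "DiagnosticPanel",
    reports = "list"
  )
)

setValidity("AmpliconAssay", function(object) {
  msg <- character()
  amp <- object@amplicon
  if (length(amp) != 1L) msg <- c(msg, "amplicon must be a single range")
  else {
    if (start(amp) != start(object@forward@footprint) ||
        end(amp) != end(object@reverse@footprint))
      msg <- c(msg, "amplicon must span forward start to reverse end")
    sites <- object@panel@sites
    if (length(sites) &&
        (any(start(sites) < start(amp)) || any(end(sites) > end(amp))))
      msg <- c(msg, "all panel sites must lie inside the amplicon")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeCount: observed genotype tallies for one variant in a cohort
#'
#' Optionally carries the allele count / percentage printed in an external
#' report so that [alleleFrequency()] can surface inconsistencies.
#'
#' @slot label Variant label (e.g. an HGVS string).
#' @slot homozygotes,heterozygotes,nIndividuals Non-negative counts with
#'   `homozygotes + heterozygotes <= nIndividuals`.
#' @slot reportedAlleles,reportedPercent Externally printed values
#'   (`NA` when absent) validated against the computed ones.
#'
#' @seealso [genotypeCount()], [alleleFrequency()]
#' @exportClass GenotypeCount
setClass("GenotypeCount",
  representation(
    label = "character",
    homozygotes = "integer",
    heterozygotes = "integer",
    nIndividuals = "integer",
    reportedAlleles = "numeric",
    reportedPercent = "numeric"
  )
)

setValidity("GenotypeCount", function(object) {
  msg <- character()
  if (object@homozygotes < 0L || object@heterozygotes < 0L || object@nIndividuals < 0L)
    msg <- c(msg, "counts must be >= 0")
  if (object@homozygotes + object@heterozygotes > object@nIndividuals)
    msg <- c(msg, "homozygotes + heterozygotes must not exceed nIndividuals")
  if (length(msg)) msg else TRUE
})
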