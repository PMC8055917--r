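#' Construct a Primer
#'
#' @param sequence 5'->3' primer sequence (reverse primers: the reverse
#'   complement of the gene top strand).
#' @param start Genomic start of the footprint on the gene top strand.
#' @param orientation `"forward"` or `"reverse"`.
#' @param contig Contig of the footprint.
#' @param tmMethod Method passed to [meltingTemperature()].
#' @return A [Primer-class].
#' @examples
#' primer("GCTCACGCAGCAAGCTGGTAAAG", 45069100, "forward", "chr15")
#' @export
primer <- function(sequence, start, orientation = c("forward", "reverse"),
                   contig = "gene", tmMethod = "nearest_neighbor") {
  orientation <- match.arg(orientation)
  sequence <- checkDna(sequence, "primer sequence", allowN = FALSE)
  fp <- gInterval(contig, as.integer(start),
                  as.integer(start) + nchar(sequence) - 1L)
  new("Primer", sequence = sequence, footprint = fp,
      orientation = orientation,
      tm = meltingTemperature(sequence, tmMethod),
      gc = gcFraction(sequence))
}

#' @rdname primer
#' @param x A [Primer-class].
#' @return `primerSequence()`, `primerFootprint()`, `primerTm()` return the
#'   corresponding slots.
#' @export
primerSequence <- function(x) x@sequence

#' @rdname primer
#' @export
primerFootprint <- function(x) x@footprint

#' @rdname primer
#' @export
primerTm <- function(x) x@tm

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer (%s): 5'-%s-3'  [%s:%d-%d]  Tm %.1f C, GC %.0f%%\n",
              object@orientation, object@sequence,
              as.character(seqnames(object@footprint)),
              start(object@footprint), end(object@footprint),
              object@tm, 100 * object@gc))
})

## Offsets (0 = 3'-terminal base) of PSV bases under a primer footprint.
psv3PrimeOffsets <- function(prm, psvs) {
  fp <- prm@footprint
  hits <- psvs[start(psvs) <= end(fp) & end(psvs) >= start(fp) &
                 as.character(seqnames(psvs)) == as.character(seqnames(fp))]
  if (!length(hits)) return(integer(0))
  if (prm@orientation == "forward")
    as.integer(end(fp) - pmin(end(hits), end(fp)))
  else
    as.integer(pmax(start(hits), start(fp)) - start(fp))
}

#' Score the gene-vs-pseudogene specificity of a primer
#'
#' A primer discriminates the gene from the pseudogene when at least one
#' PSV lies within the last `window` bases of its 3' end, where a mismatch
#' most strongly disrupts hybridisation on the pseudogene template.
#'
#' @param prm A [Primer-class].
#' @param psvs PSV `GRanges` (see [enumeratePsvs()]).
#' @param window 3'-end window in bases (default 3).
#' @return A [SpecificityReport-class] (SNP fields empty; see
#'   [checkSnpCollision()]).
#' @export
specificityScore <- function(prm, psvs, window = 3L) {
  stopifnot(is(prm, "Primer"), window >= 1L)
  off <- sort(psv3PrimeOffsets(prm, psvs))
  new("SpecificityReport",
      psvOffsets = off,
      min3PrimeOffset = if (length(off)) min(off) else Inf,
      isSpecific = any(off < window),
      collidingSnps = GRanges(),
      dropoutRisk = FALSE)
}

#' Check a primer footprint for frequent-SNP collisions
#'
#' A frequent polymorphism (population frequency strictly above
#' `threshold`) under a primer can prevent amplification of one allele
#' (allele dropout) and yield a false homozygous result.
#'
#' @param prm A [Primer-class].
#' @param table A [FrequencyTable-class].
#' @param threshold Frequency threshold (default 0.01, the ">1%" rule).
#' @return A list with `collidingSnps` (variant `GRanges`) and
#'   `dropoutRisk` (logical).
#' @export
checkSnpCollision <- function(prm, table, threshold = 0.01) {
  stopifnot(is(prm, "Primer"))
  snps <- frequentVariantsInFootprint(table, prm@footprint, threshold)
  list(collidingSnps = snps, dropoutRisk = length(snps) > 0L)
}

fullSpecificityReport <- function(prm, psvs, table, window = 3L,
                                  threshold = 0.01) {
  sp <- specificityScore(prm, psvs, window)
  snp <- checkSnpCollision(prm, table, threshold)
  new("SpecificityReport",
      psvOffsets = sp@psvOffsets,
      min3PrimeOffset = sp@min3PrimeOffset,
      isSpecific = sp@isSpecific,
      collidingSnps = snp$collidingSnps,
      dropoutRisk = snp$dropoutRisk)
}

setMethod("show", "SpecificityReport", function(object) {
  cat(sprintf(
    "SpecificityReport: %s (PSV 3'-offsets: %s); dropout risk: %s (%d SNP(s))\n",
    if (object@isSpecific) "specific" else "NOT specific",
    if (length(object@psvOffsets)) paste(object@psvOffsets, collapse = ",")
    else "none",
    if (object@dropoutRisk) "yes" else "no",
    length(object@collidingSnps)))
})

#' Primer candidate constraints
#'
#' Standard-practice defaults: length 18-27 nt, GC 0.35-0.65,
#' nearest-neighbor Tm 57-63 degrees C with a 60 degree target, a 3-base 3'
#' specificity window and a 1% SNP-collision threshold.  All are
#' configurable.
#'
#' @param lengthRange,gcRange,tmRange Two-element min/max vectors.
#' @param tmTarget Ranking target Tm.
#' @param window 3'-end specificity window (bases).
#' @param snpThreshold Frequency threshold for [checkSnpCollision()].
#' @return A list of constraints for [generatePrimerCandidates()].
#' @export
primerConstraints <- function(lengthRange = c(18L, 27L),
                              gcRange = c(0.35, 0.65),
                              tmRange = c(57, 63), tmTarget = 60,
                              window = 3L, snpThreshold = 0.01) {
  list(lengthRange = as.integer(lengthRange), gcRange = gcRange,
       tmRange = tmRange, tmTarget = tmTarget, window = as.integer(window),
       snpThreshold = snpThreshold)
}

designFailure <- function(stage, detail) {
  structure(list(stage = stage, detail = detail),
            class = c("psvkitDesignFailure", "list"))
}

#' Generate ranked gene-specific primer candidates
#'
#' Enumerates every substring of `region` within the length constraints and
#' keeps candidates that (i) place at least one PSV within the 3' window
#' (gene-specific), (ii) cover no population variant above the SNP
#' threshold (no allele-dropout risk), and (iii) satisfy Tm and GC bounds.
#' Candidates are ranked by 3'-offset of the nearest PSV (ascending), then
#' distance from the target Tm, then leftmost position, so designs are
#' reproducible.
#'
#' @param geneSeq Gene sequence (plus strand).
#' @param region Single-range [GenomicRanges::GRanges] to search, in the
#'   coordinate frame of `geneOrigin`.
#' @param psvs PSV `GRanges`.
#' @param table A [FrequencyTable-class].
#' @param constraints See [primerConstraints()].
#' @param orientation `"forward"` or `"reverse"`.
#' @param geneOrigin Genomic origin of `geneSeq` (default `<contig>:1`
#'   using the region's contig).
#' @param requireSpecific Set `FALSE` to drop the PSV requirement (used for
#'   internal sequencing primers, where only SNP avoidance is mandatory).
#' @param maxCandidates Cap on the number of returned primers (default 50);
#'   ranking is computed over all eligible candidates first.
#' @return A list of [Primer-class] objects, best first.  When empty, the
#'   attribute `"failure"` holds a machine-readable reason
#'   (`stage` one of `"no paralog-discriminating site"`,
#'   `"snp_collision"`, `"thermodynamic_constraints"`, `"empty_region"`).
#' @export
generatePrimerCandidates <- function(geneSeq, region, psvs, table,
                                     constraints = primerConstraints(),
                                     orientation = c("forward", "reverse"),
                                     geneOrigin = NULL,
                                     requireSpecific = TRUE,
                                     maxCandidates = 50L) {
  orientation <- match.arg(orientation)
  geneSeq <- checkDna(geneSeq, "geneSeq")
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  contig <- as.character(seqnames(region))
  if (is.null(geneOrigin)) geneOrigin <- gInterval(contig, 1L, nchar(geneSeq))
  off <- start(geneOrigin) - 1L
  L <- nchar(geneSeq)
  lo <- max(start(region) - off, 1L)
  hi <- min(end(region) - off, L)
  fail <- function(stage, detail) {
    res <- list()
    attr(res, "failure") <- designFailure(stage, detail)
    res
  }
  if (hi < lo) return(fail("empty_region", "region outside the gene sequence"))

  chars <- strsplit(geneSeq, "")[[1L]]
  ## per-position masks in gene-sequence coordinates
  clipMask <- function(gr, keep) {
    mask <- logical(L)
    gr <- gr[keep & as.character(seqnames(gr)) == contig]
    for (i in seq_along(gr)) {
      s <- max(start(gr)[i] - off, 1L); e <- min(end(gr)[i] - off, L)
      if (s <= e) mask[s:e] <- TRUE
    }
    mask
  }
  psvMask <- clipMask(psvs, rep(TRUE, length(psvs)))
  tableVars <- variants(table)
  snpMask <- clipMask(tableVars,
                      if (length(tableVars))
                        mcols(tableVars)$frequency > constraints$snpThreshold
                      else logical(0))
  snpCum <- c(0L, cumsum(snpMask))
  nCum <- c(0L, cumsum(chars == "N"))
  gcCum <- c(0L, cumsum(chars %in% c("G", "C")))
  ## nearest PSV base at-or-before / at-or-after each position
  idx <- seq_len(L)
  lastPsv <- cummax(ifelse(psvMask, idx, 0L))
  firstPsv <- rev(cummin(rev(ifelse(psvMask, idx, L + 1L))))

  lens <- seq.int(constraints$lengthRange[1L], constraints$lengthRange[2L])
  starts <- integer(0); lenv <- integer(0)
  for (len in lens) {
    if (hi - lo + 1L < len) next
    s <- lo:(hi - len + 1L)
    starts <- c(starts, s)
    lenv <- c(lenv, rep_len(len, length(s)))
  }
  if (!length(starts)) {
    if (requireSpecific && length(psvsInInterval(psvs, region)) == 0L)
      return(fail("no paralog-discriminating site",
                  "no PSV inside the search region"))
    return(fail("thermodynamic_constraints",
                "region is shorter than the minimum primer length"))
  }
  ends <- starts + lenv - 1L

  ## 3'-end offsets to the nearest in-footprint PSV base
  minOff <- if (orientation == "forward") {
    o <- ends - lastPsv[ends]
    ifelse(lastPsv[ends] >= starts, o, Inf)
  } else {
    o <- firstPsv[starts] - starts
    ifelse(firstPsv[starts] <= ends, o, Inf)
  }
  specific <- minOff < constraints$window
  noN <- (nCum[ends + 1L] - nCum[starts]) == 0L
  noSnp <- (snpCum[ends + 1L] - snpCum[starts]) == 0L
  gc <- (gcCum[ends + 1L] - gcCum[starts]) / lenv
  tm <- .nnTm(chars, starts, ends)
  thermoOk <- gc >= constraints$gcRange[1L] & gc <= constraints$gcRange[2L] &
    tm >= constraints$tmRange[1L] & tm <= constraints$tmRange[2L]

  keepSpec <- noN & (!requireSpecific | specific)
  keep <- keepSpec & noSnp & thermoOk
  if (!any(keep)) {
    if (requireSpecific && length(psvsInInterval(psvs, region)) == 0L)
      return(fail("no paralog-discriminating site",
                  "no PSV inside the search region"))
    if (requireSpecific && !any(noN & specific))
      return(fail("no paralog-discriminating site",
                  "no candidate places a PSV in its 3' window"))
    if (!any(keepSpec & noSnp))
      return(fail("snp_collision",
                  "every otherwise-eligible candidate covers a frequent SNP"))
    return(fail("thermodynamic_constraints",
                "no candidate satisfies the Tm/GC constraints"))
  }
  o <- order(minOff[keep], abs(tm[keep] - constraints$tmTarget),
             starts[keep])
  pick <- which(keep)[o]
  pick <- pick[seq_len(min(length(pick), maxCandidates))]
  lapply(pick, function(i) {
    top <- substr(geneSeq, starts[i], ends[i])
    primer(if (orientation == "forward") top else revComp(top),
           starts[i] + off, orientation, contig)
  })
}
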