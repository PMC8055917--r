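#' Assay design configuration
#'
#' @param constraints Primer constraints, see [primerConstraints()].
#' @param binding Binding model for in-silico PCR, see [bindingModel()].
#' @param maxFlank How far (bases) beyond each side of the target region to
#'   search for PCR primers (default 120).
#' @param k Diagnostic panel size (default 3; the recommended number of
#'   control SNPs per amplicon).
#' @param excludeTarget Label(s) of the assay's target variant site(s),
#'   never eligible for the panel.
#' @param maxFreqWarn Panel warning threshold, see [selectPanel()].
#' @param pairLimit How many top-ranked candidates per side to try in the
#'   in-silico PCR stage (default 8).
#' @param sequencingPrimer Design an internal sequencing primer (default
#'   `TRUE`).
#' @return A configuration list for [designAssay()].
#' @export
assayConfig <- function(constraints = primerConstraints(),
                        binding = bindingModel(),
                        maxFlank = 120L, k = 3L,
                        excludeTarget = character(0),
                        maxFreqWarn = 0.05,
                        pairLimit = 8L,
                        sequencingPrimer = TRUE) {
  list(constraints = constraints, binding = binding,
       maxFlank = as.integer(maxFlank), k = as.integer(k),
       excludeTarget = excludeTarget, maxFreqWarn = maxFreqWarn,
       pairLimit = as.integer(pairLimit),
       sequencingPrimer = sequencingPrimer)
}

designError <- function(stage, detail) {
  stop(errorCondition(
    sprintf("assay design infeasible at stage '%s': %s", stage, detail),
    stage = stage, detail = detail,
    class = c("psvkitDesignError", "error", "condition")))
}

candidateFailure <- function(cands, fallbackStage) {
  f <- attr(cands, "failure")
  if (is.null(f)) designError(fallbackStage, "no candidate found")
  designError(f$stage, f$detail)
}

#' Design a gene-specific amplicon assay end to end
#'
#' Pipeline: align the gene to the pseudogene, enumerate PSVs, generate
#' ranked forward/reverse primer candidates flanking the target region
#' (each primer must place a PSV in its 3' window and avoid frequent SNPs),
#' then accept the first pair whose in-silico PCR yields exactly one
#' product on the gene and none on the pseudogene.  An internal sequencing
#' primer is chosen inside the amplicon subject to the SNP-collision rule,
#' and a diagnostic SNP panel of `k` PSV sites is attached.
#'
#' @param geneSeq,pseudoSeq Gene and pseudogene sequences.
#' @param region Single-range [GenomicRanges::GRanges]: the target to
#'   amplify (e.g. one exon), in the frame of `geneOrigin`.
#' @param table A [FrequencyTable-class] of population variants (default
#'   empty).
#' @param config See [assayConfig()].
#' @param geneOrigin Genomic origin of `geneSeq` (default `<contig>:1`).
#' @return An [AmpliconAssay-class].  On infeasibility an error of class
#'   `psvkitDesignError` is signalled whose `stage` field names the stage
#'   that exhausted its candidates (e.g. `"no paralog-discriminating
#'   site"`).
#' @export
designAssay <- function(geneSeq, pseudoSeq, region,
                        table = frequencyTable(), config = assayConfig(),
                        geneOrigin = NULL) {
  geneSeq <- checkDna(geneSeq, "geneSeq")
  pseudoSeq <- checkDna(pseudoSeq, "pseudoSeq")
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  contig <- as.character(seqnames(region))
  if (is.null(geneOrigin)) geneOrigin <- gInterval(contig, 1L, nchar(geneSeq))
  off <- start(geneOrigin) - 1L

  aln <- alignParalogs(geneSeq, pseudoSeq, geneOrigin = geneOrigin)
  psvs <- enumeratePsvs(aln)
  if (!length(psvs))
    designError("no paralog-discriminating site",
                "gene and pseudogene have no sequence difference")

  minLen <- config$constraints$lengthRange[1L]
  fwdWin <- gInterval(contig,
                      max(off + 1L, start(region) - config$maxFlank),
                      start(region) - 1L)
  if (width(fwdWin) < minLen)
    designError("forward_window", "no room for a forward primer upstream of the region")
  revWin <- gInterval(contig, end(region) + 1L,
                      min(off + nchar(geneSeq), end(region) + config$maxFlank))
  if (width(revWin) < minLen)
    designError("reverse_window", "no room for a reverse primer downstream of the region")

  fwd <- generatePrimerCandidates(geneSeq, fwdWin, psvs, table,
                                  config$constraints, "forward", geneOrigin,
                                  maxCandidates = config$pairLimit)
  if (!length(fwd)) candidateFailure(fwd, "forward_candidates")
  rvs <- generatePrimerCandidates(geneSeq, revWin, psvs, table,
                                  config$constraints, "reverse", geneOrigin,
                                  maxCandidates = config$pairLimit)
  if (!length(rvs)) candidateFailure(rvs, "reverse_candidates")

  nF <- min(length(fwd), config$pairLimit)
  nR <- min(length(rvs), config$pairLimit)
  pairs <- expand.grid(i = seq_len(nF), j = seq_len(nR))
  pairs <- pairs[order(pairs$i + pairs$j, pairs$i), , drop = FALSE]
  chosen <- NULL
  for (r in seq_len(nrow(pairs))) {
    f <- fwd[[pairs$i[r]]]; rv <- rvs[[pairs$j[r]]]
    onPseudo <- inSilicoPcr(f, rv, pseudoSeq, config$binding)
    if (nrow(onPseudo) > 0L) next
    onGene <- inSilicoPcr(f, rv, geneSeq, config$binding)
    if (nrow(onGene) != 1L) next
    chosen <- list(f = f, r = rv)
    break
  }
  if (is.null(chosen))
    designError("in_silico_pcr",
                "every candidate pair either co-amplifies the pseudogene or fails to amplify the gene uniquely")

  amplicon <- gInterval(contig, start(chosen$f@footprint),
                        end(chosen$r@footprint))
  ampPsvs <- psvsInInterval(psvs, amplicon)

  seqPrimer <- NULL
  if (isTRUE(config$sequencingPrimer)) {
    seqWin <- gInterval(contig,
                        min(end(chosen$f@footprint) + 1L, end(amplicon)),
                        max(start(region) - 1L, end(chosen$f@footprint) + 1L))
    if (width(seqWin) >= minLen) {
      sp <- generatePrimerCandidates(geneSeq, seqWin, psvs, table,
                                     config$constraints, "forward",
                                     geneOrigin, requireSpecific = FALSE,
                                     maxCandidates = 1L)
      if (length(sp)) seqPrimer <- sp[[1L]]
    }
  }

  annotated <- annotatePsvFrequencies(ampPsvs, table)
  panel <- selectPanel(annotated, amplicon, k = config$k,
                       exclude = config$excludeTarget,
                       maxFreqWarn = config$maxFreqWarn)

  reports <- list(
    forward = fullSpecificityReport(chosen$f, psvs, table,
                                    config$constraints$window,
                                    config$constraints$snpThreshold),
    reverse = fullSpecificityReport(chosen$r, psvs, table,
                                    config$constraints$window,
                                    config$constraints$snpThreshold))
  if (!is.null(seqPrimer))
    reports$sequencing <- fullSpecificityReport(
      seqPrimer, psvs, table, config$constraints$window,
      config$constraints$snpThreshold)

  new("AmpliconAssay",
      forward = chosen$f, reverse = chosen$r,
      sequencingPrimer = seqPrimer, amplicon = amplicon,
      psvs = ampPsvs, panel = panel, reports = reports)
}

setMethod("show", "AmpliconAssay", function(object) {
  cat(sprintf("AmpliconAssay: %s:%d-%d (%d bp), %d PSV(s) in amplicon\n",
              as.character(seqnames(object@amplicon)),
              start(object@amplicon), end(object@amplicon),
              width(object@amplicon), length(object@psvs)))
  cat("  forward:    "); show(object@forward)
  cat("  reverse:    "); show(object@reverse)
  if (!is.null(object@sequencingPrimer)) {
    cat("  sequencing: "); show(object@sequencingPrimer)
  }
  cat(sprintf("  panel: %s\n",
              paste(mcols(object@panel@sites)$label, collapse = ", ")))
})

#' @rdname designAssay
#' @param assay An [AmpliconAssay-class].
#' @return `assayPanel()` / `assayAmplicon()` / `assayPrimers()` return the
#'   panel, the amplicon range, and a named list of primers.
#' @export
assayPanel <- function(assay) assay@panel

#' @rdname designAssay
#' @export
assayAmplicon <- function(assay) assay@amplicon

#' @rdname designAssay
#' @export
assayPrimers <- function(assay) {
  out <- list(forward = assay@forward, reverse = assay@reverse)
  if (!is.null(assay@sequencingPrimer))
    out$sequencing <- assay@sequencingPrimer
  out
}
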