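#' Alignment scoring parameters
#'
#' Default scoring is blastn-like: match +2, mismatch -3, and an affine gap
#' penalty where a gap of length L costs `gapOpening + L * gapExtension`
#' (5 + 2L by default).  N is scored as a mismatch against every base,
#' including N itself, so ambiguous bases never count as identity.
#'
#' @param match,mismatch Substitution scores.
#' @param gapOpening,gapExtension Non-negative gap costs.
#' @return A list of scoring parameters for [alignParalogs()].
#' @export
alignmentScoring <- function(match = 2, mismatch = -3,
                             gapOpening = 5, gapExtension = 2) {
  stopifnot(gapOpening >= 0, gapExtension >= 0, match > mismatch)
  list(match = match, mismatch = mismatch,
       gapOpening = gapOpening, gapExtension = gapExtension)
}

substitutionMatrix5 <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Globally align a gene to its pseudogene
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' \code{Biostrings::pairwiseAlignment}) under blastn-like default scoring;
#' the alignment is optimal and deterministic for fixed inputs and scoring.
#'
#' @param geneSeq,pseudoSeq Nucleotide sequences (character, `DNAString`);
#'   alphabet \{A,C,G,T,N\}; case-insensitive.
#' @param scoring Scoring parameters from [alignmentScoring()].
#' @param geneOrigin Optional single-range [GenomicRanges::GRanges] giving
#'   the genomic position of the first gene base (defaults to `gene:1`,
#'   plus strand); all PSV coordinates are reported in this frame.
#' @return A [ParalogAlignment-class] object.
#' @examples
#' aln <- alignParalogs("ACGTACGT", "ACGACGT")
#' identityStats(aln)
#' @export
alignParalogs <- function(geneSeq, pseudoSeq, scoring = alignmentScoring(),
                          geneOrigin = NULL) {
  geneSeq <- checkDna(geneSeq, "geneSeq")
  pseudoSeq <- checkDna(pseudoSeq, "pseudoSeq")
  if (is.null(geneOrigin))
    geneOrigin <- gInterval("gene", 1L, nchar(geneSeq))
  stopifnot(is(geneOrigin, "GRanges"), length(geneOrigin) == 1L)
  pa <- Biostrings::pairwiseAlignment(
    pattern = geneSeq, subject = pseudoSeq, type = "global",
    substitutionMatrix = substitutionMatrix5(scoring),
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension
  )
  ga <- as.character(Biostrings::alignedPattern(pa))
  pb <- as.character(Biostrings::alignedSubject(pa))
  gch <- strsplit(ga, "")[[1L]]
  colMap <- as.integer(cumsum(gch != "-"))
  new("ParalogAlignment",
      geneAligned = unname(ga), pseudoAligned = unname(pb),
      score = unname(Biostrings::score(pa)),
      geneOrigin = geneOrigin, columnToGenePos = colMap,
      scoring = scoring)
}

#' @describeIn alignParalogs Gapped gene row of the alignment.
#' @param aln A [ParalogAlignment-class].
#' @export
geneAligned <- function(aln) aln@geneAligned

#' @describeIn alignParalogs Gapped pseudogene row of the alignment.
#' @export
pseudoAligned <- function(aln) aln@pseudoAligned

#' @describeIn alignParalogs Alignment score.
#' @export
alignmentScore <- function(aln) aln@score

setMethod("show", "ParalogAlignment", function(object) {
  st <- identityStats(object)
  cat(sprintf("ParalogAlignment: %d columns, score %.1f\n",
              nchar(object@geneAligned), object@score))
  cat(sprintf("  identity %d/%d, %d gap column(s) in %d run(s)\n",
              st@identical, st@alignedLength, st@gapColumns, st@gapRuns))
  cat(sprintf("  gene origin: %s:%d\n",
              as.character(seqnames(object@geneOrigin)),
              start(object@geneOrigin)))
})

alignmentColumns <- function(aln) {
  g <- strsplit(aln@geneAligned, "")[[1L]]
  p <- strsplit(aln@pseudoAligned, "")[[1L]]
  list(g = g, p = p,
       gGap = g == "-", pGap = p == "-",
       hasN = g == "N" | p == "N")
}

countRuns <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  sum(r$values)
}

#' Column-wise identity statistics of a paralog alignment
#'
#' Tallies identical columns, mismatches and gap columns; contiguous gap
#' columns in one row form a single gap run (e.g. a 2295/2320 identity with
#' three gaps).  Columns containing N never count as identical.
#'
#' @param aln A [ParalogAlignment-class] from [alignParalogs()].
#' @return An [IdentityStats-class] object.
#' @export
identityStats <- function(aln) {
  stopifnot(is(aln, "ParalogAlignment"))
  cols <- alignmentColumns(aln)
  gap <- cols$gGap | cols$pGap
  ident <- !gap & !cols$hasN & cols$g == cols$p
  mism <- !gap & !ident
  new("IdentityStats",
      alignedLength = length(cols$g),
      identical = sum(ident),
      mismatches = sum(mism),
      gapColumns = sum(gap),
      gapRuns = countRuns(cols$gGap) + countRuns(cols$pGap))
}

setMethod("show", "IdentityStats", function(object) {
  cat(sprintf(
    "IdentityStats: %d/%d identical, %d mismatch(es), %d gap column(s) in %d run(s)\n",
    object@identical, object@alignedLength, object@mismatches,
    object@gapColumns, object@gapRuns))
})

#' @rdname identityStats
#' @return `identityVector()` returns the tallies as a named integer vector.
#' @export
identityVector <- function(aln) {
  st <- if (is(aln, "IdentityStats")) aln else identityStats(aln)
  c(alignedLength = st@alignedLength, identical = st@identical,
    mismatches = st@mismatches, gapColumns = st@gapColumns,
    gapRuns = st@gapRuns)
}

#' Enumerate paralog-specific variants from a paralog alignment
#'
#' Scans the alignment columns and emits one PSV per maximal run of
#' same-type difference columns: contiguous mismatch columns merge into one
#' substitution, contiguous gap columns in one row merge into one indel.
#' Indels are normalized to their 3'-most equivalent position (the HGVS
#' convention; note VCF left-alignment shifts the other way).  Runs
#' containing N are flagged `ambiguous`; runs consisting only of N columns
#' are never PSV-defining and are dropped.
#'
#' @param aln A [ParalogAlignment-class] with its genomic origin set.
#' @return A PSV `GRanges` (see [psvRanges()]) sorted by gene coordinate.
#' @examples
#' aln <- alignParalogs("ACGTACGT", "ACGACGT",
#'                      geneOrigin = GenomicRanges::GRanges("g", IRanges::IRanges(101, 108)))
#' enumeratePsvs(aln)
#' @export
enumeratePsvs <- function(aln) {
  stopifnot(is(aln, "ParalogAlignment"))
  cols <- alignmentColumns(aln)
  geneChars <- cols$g[!cols$gGap]
  contig <- as.character(seqnames(aln@geneOrigin))
  originStart <- start(aln@geneOrigin)

  ## column type: 0 identical-ish (incl. N-only equality), 1 mismatch,
  ## 2 gap in pseudo (deletion from pseudogene), 3 gap in gene (insertion)
  type <- integer(length(cols$g))
  type[!cols$gGap & !cols$pGap & (cols$g != cols$p | cols$hasN)] <- 1L
  type[!cols$gGap & !cols$pGap & cols$g == cols$p & !cols$hasN] <- 0L
  type[cols$pGap] <- 2L
  type[cols$gGap] <- 3L

  r <- rle(type)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  out <- list()
  for (i in seq_along(r$values)) {
    tp <- r$values[i]
    if (tp == 0L) next
    idx <- starts[i]:ends[i]
    gAll <- paste(cols$g[idx][cols$g[idx] != "-"], collapse = "")
    pAll <- paste(cols$p[idx][cols$p[idx] != "-"], collapse = "")
    amb <- any(cols$hasN[idx])
    if (tp == 1L) {
      ## substitution run; drop if every column is N-driven
      nOnly <- all(cols$g[idx] == "N" | cols$p[idx] == "N")
      if (nOnly) next
      s <- aln@columnToGenePos[idx[1L]]
      e <- aln@columnToGenePos[idx[length(idx)]]
      out[[length(out) + 1L]] <- list(kind = "substitution", s = s, e = e,
                                      ga = gAll, pa = pAll, amb = amb)
    } else if (tp == 2L) {
      ## gene bases absent from the pseudogene
      s <- aln@columnToGenePos[idx[1L]]
      sh <- shift3Prime(geneChars, "deletion", s, gAll)
      out[[length(out) + 1L]] <- list(kind = "deletion", s = sh$pos,
                                      e = sh$pos + nchar(sh$allele) - 1L,
                                      ga = sh$allele, pa = "", amb = amb)
    } else {
      ## extra pseudogene bases; anchor at preceding gene base
      anchor <- aln@columnToGenePos[idx[1L]]
      sh <- shift3Prime(geneChars, "insertion", anchor, pAll)
      out[[length(out) + 1L]] <- list(kind = "insertion", s = sh$pos,
                                      e = sh$pos, ga = "", pa = sh$allele,
                                      amb = amb)
    }
  }
  if (!length(out))
    return(psvRanges(contig, integer(0), integer(0), character(0),
                     character(0), character(0)))
  off <- originStart - 1L
  psvRanges(contig,
            start = vapply(out, `[[`, 0L, "s") + off,
            end = vapply(out, `[[`, 0L, "e") + off,
            kind = vapply(out, `[[`, "", "kind"),
            geneAllele = vapply(out, `[[`, "", "ga"),
            pseudoAllele = vapply(out, `[[`, "", "pa"),
            ambiguous = vapply(out, `[[`, TRUE, "amb"))
}

#' Subset PSVs to a genomic interval
#'
#' Returns the PSVs whose gene interval intersects `region` (inclusive
#' endpoints), preserving order.
#'
#' @param psvs A PSV `GRanges`.
#' @param region A single-range [GenomicRanges::GRanges] on the same contig.
#' @return The intersecting subset of `psvs`.
#' @export
psvsInInterval <- function(psvs, region) {
  stopifnot(is(psvs, "GRanges"), is(region, "GRanges"), length(region) == 1L)
  if (length(psvs) &&
      !all(as.character(seqnames(psvs)) == as.character(seqnames(region))))
    stop("coordinate error: PSVs and region are on different contigs",
         call. = FALSE)
  psvs[start(psvs) <= end(region) & end(psvs) >= start(region)]
}

#' Write a two-row gapped alignment dump
#'
#' @param aln A [ParalogAlignment-class].
#' @param path Output file; two lines, gene row then pseudogene row.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  writeLines(c(aln@geneAligned, aln@pseudoAligned), path)
  invisible(path)
}
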