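#' Construct a transcript model
#'
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons A [GenomicRanges::GRanges] or [IRanges::IRanges] of exons in
#'   genomic coordinates; they are re-ordered 5'->3' in transcript
#'   orientation.
#' @param cdsStartOffset Bases into the spliced transcript before c.1
#'   (default 0: the transcript starts at the CDS).
#' @return A [TranscriptModel-class].
#' @examples
#' tm <- transcriptModel("chr1", "+", IRanges::IRanges(c(101, 201), c(150, 260)))
#' mapCoordinates(tm, 60)  # -> 210
#' @export
transcriptModel <- function(contig, strand = c("+", "-"), exons,
                            cdsStartOffset = 0L) {
  strand <- match.arg(strand)
  if (is(exons, "IRanges"))
    exons <- GRanges(contig, exons, strand = strand)
  stopifnot(is(exons, "GRanges"))
  o <- order(start(exons))
  if (strand == "-") o <- rev(o)
  new("TranscriptModel", contig = contig, strand = strand,
      exons = granges(exons)[o], cdsStartOffset = as.integer(cdsStartOffset))
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel on %s(%s): %d exon(s), spliced length %d, c.1 at offset %d\n",
              object@contig, object@strand, length(object@exons),
              sum(width(object@exons)), object@cdsStartOffset))
})

#' Map cDNA (c.) positions to genomic (g.) positions and back
#'
#' `mapCoordinates()` converts a coding (c.) position into its 1-based
#' genomic position by walking the exon structure in transcript
#' orientation; `mapGenomic()` is its exact inverse for exonic positions.
#'
#' @param model A [TranscriptModel-class].
#' @param cPosition Coding (c.) position(s), 1-based, within the coding
#'   length of the model.
#' @return `mapCoordinates()`: genomic position(s); `mapGenomic()`: c.
#'   position(s).
#' @examples
#' tm <- transcriptModel("chr1", "+", IRanges::IRanges(101, 150))
#' mapCoordinates(tm, 1)   # 101
#' mapGenomic(tm, 101)     # 1
#' @export
mapCoordinates <- function(model, cPosition) {
  stopifnot(is(model, "TranscriptModel"))
  cPosition <- as.integer(cPosition)
  w <- width(model@exons)
  total <- sum(w)
  vapply(cPosition, function(cp) {
    if (is.na(cp) || cp < 1L)
      stop("range error: c. position must be >= 1", call. = FALSE)
    sp <- model@cdsStartOffset + cp       # position in spliced transcript
    if (sp > total)
      stop(sprintf("range error: c.%d lies beyond the transcript (spliced length %d)",
                   cp, total), call. = FALSE)
    cum <- cumsum(w)
    i <- which(sp <= cum)[1L]
    off <- sp - c(0L, cum)[i]             # 1-based offset within exon i
    ex <- model@exons[i]
    if (model@strand == "+") start(ex) + off - 1L else end(ex) - off + 1L
  }, integer(1L))
}

#' @rdname mapCoordinates
#' @param gPosition Genomic position(s); must be exonic.
#' @export
mapGenomic <- function(model, gPosition) {
  stopifnot(is(model, "TranscriptModel"))
  gPosition <- as.integer(gPosition)
  w <- width(model@exons)
  cumBefore <- c(0L, cumsum(w))[seq_along(w)]
  vapply(gPosition, function(gp) {
    i <- which(gp >= start(model@exons) & gp <= end(model@exons))
    if (!length(i))
      stop(sprintf("not-exonic error: g.%d is not inside any exon", gp),
           call. = FALSE)
    i <- i[1L]
    ex <- model@exons[i]
    off <- if (model@strand == "+") gp - start(ex) + 1L else end(ex) - gp + 1L
    cp <- cumBefore[i] + off - model@cdsStartOffset
    if (cp < 1L)
      stop(sprintf("range error: g.%d lies 5' of the coding start", gp),
           call. = FALSE)
    cp
  }, integer(1L))
}
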