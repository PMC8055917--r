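## Internal helpers shared across modules.

## Uppercase and validate a nucleotide sequence.  `what` names the argument
## in error messages; N is allowed only when allowN = TRUE.
checkDna <- function(x, what = "sequence", allowN = TRUE) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  x <- toupper(x)
  if (nchar(x) == 0L)
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  pat <- if (allowN) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x))
    stop(sprintf("%s contains non-nucleotide characters (alphabet %s)",
                 what, if (allowN) "{A,C,G,T,N}" else "{A,C,G,T}"),
         call. = FALSE)
  x
}

gcFraction <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Parse "chr:start-end" into a GRanges (1-based inclusive).
parseRegion <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1L]]
  if (length(m) != 4L)
    stop("region must be given as 'contig:start-end'", call. = FALSE)
  GRanges(m[2L], IRanges(as.integer(m[3L]), as.integer(m[4L])))
}

## Single-range genomic interval constructor used throughout.
gInterval <- function(contig, start, end = start, strand = "+") {
  stopifnot(start >= 1L, end >= start)
  GRanges(contig, IRanges(start, end), strand = strand)
}

## HGVS-g-style label for a PSV; reproducible from the PSV fields.
hgvsLabel <- function(kind, start, end, geneAllele, pseudoAllele) {
  mapply(function(k, s, e, ga, pa) {
    switch(k,
      substitution = if (nchar(ga) == 1L)
        sprintf("g.%d%s>%s", s, ga, pa)
      else
        sprintf("g.%d_%ddelins%s", s, e, pa),
      deletion = if (s == e) sprintf("g.%ddel", s)
        else sprintf("g.%d_%ddel", s, e),
      insertion = sprintf("g.%d_%dins%s", s, s + 1L, pa),
      stop("unknown PSV kind: ", k)
    )
  }, kind, start, end, geneAllele, pseudoAllele, USE.NAMES = FALSE)
}

## 3'-most (HGVS) normalization of an indel against the full gene sequence.
## `pos` is the 1-based gene position of the first deleted base (deletion)
## or of the base preceding the insertion point (insertion); `allele` is the
## deleted/inserted sequence.  Returns list(pos, allele).  Note this is the
## opposite shift direction from VCF left-alignment.
shift3Prime <- function(geneChars, kind, pos, allele) {
  L <- length(geneChars)
  n <- nchar(allele)
  if (kind == "deletion") {
    while (pos + n <= L && geneChars[pos + n] == geneChars[pos]) {
      pos <- pos + 1L
    }
    allele <- paste(geneChars[pos:(pos + n - 1L)], collapse = "")
  } else if (kind == "insertion") {
    while (pos + 1L <= L && geneChars[pos + 1L] == substr(allele, 1L, 1L)) {
      pos <- pos + 1L
      allele <- paste0(substr(allele, 2L, n), substr(allele, 1L, 1L))
    }
  }
  list(pos = pos, allele = allele)
}

#' Construct a PSV GRanges
#'
#' PSVs (paralog-specific variants) are represented as a
#' [GenomicRanges::GRanges] with metadata columns `kind` (`substitution`,
#' `deletion` = bases present in the gene but absent from the pseudogene,
#' `insertion` = extra bases in the pseudogene), `geneAllele`,
#' `pseudoAllele`, `label` (HGVS-g style) and `ambiguous` (run contained N
#' bases).  Intervals are 1-based inclusive on the gene; insertions are
#' anchored at the gene base preceding the insertion point.
#'
#' @param contig Contig name(s).
#' @param start,end 1-based inclusive gene coordinates.
#' @param kind One of `"substitution"`, `"deletion"`, `"insertion"` per PSV.
#' @param geneAllele,pseudoAllele Allele sequences; exactly one may be empty
#'   (the gene allele for an insertion, the pseudogene allele for a
#'   deletion).
#' @param label Optional HGVS-style labels; derived from the fields when
#'   `NULL`.
#' @param ambiguous Logical flag(s): the underlying alignment run contained
#'   N bases.
#' @return A `GRanges` with the PSV metadata columns, sorted by position.
#' @examples
#' psvRanges("chr15", 45069043, 45069043, "substitution", "G", "A")
#' @export
psvRanges <- function(contig, start, end, kind, geneAllele, pseudoAllele,
                      label = NULL, ambiguous = FALSE) {
  n <- length(start)
  kind <- rep_len(kind, n)
  geneAllele <- rep_len(as.character(geneAllele), n)
  pseudoAllele <- rep_len(as.character(pseudoAllele), n)
  ambiguous <- rep_len(ambiguous, n)
  bad <- (geneAllele == "") & (pseudoAllele == "")
  if (any(bad)) stop("a PSV may not have both alleles empty")
  subs <- kind == "substitution"
  if (any(subs & (nchar(geneAllele) != nchar(pseudoAllele) |
                  geneAllele == "" | pseudoAllele == "")))
    stop("substitution PSVs need equal-length non-empty alleles")
  if (is.null(label))
    label <- hgvsLabel(kind, start, end, geneAllele, pseudoAllele)
  gr <- GRanges(rep_len(contig, n), IRanges(start, end))
  mcols(gr)$kind <- kind
  mcols(gr)$geneAllele <- geneAllele
  mcols(gr)$pseudoAllele <- pseudoAllele
  mcols(gr)$label <- label
  mcols(gr)$ambiguous <- ambiguous
  gr[order(start(gr), end(gr))]
}
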