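#' Construct a frequency table of population variants
#'
#' @param contig,pos Variant locations (1-based position of the first ref
#'   base).
#' @param ref,alt Reference (gene) and alternate alleles; for indels, use
#'   either anchored VCF-style alleles (`"CA"`/`"C"`) or a bare `""` side
#'   with 3'-normalized coordinates.
#' @param frequency Population allele frequency as a fraction in \[0,1\].
#' @param source Free-text provenance label (e.g. `"gnomAD"`).
#' @return A [FrequencyTable-class].
#' @examples
#' frequencyTable("chr15", 45069181, "A", "C", 0.2194)
#' @export
frequencyTable <- function(contig = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           frequency = numeric(0), source = "user") {
  n <- length(pos)
  gr <- GRanges(rep_len(contig, max(n, 0L)),
                IRanges(pos, pos + pmax(nchar(ref) - 1L, 0L)))
  mcols(gr)$ref <- as.character(ref)
  mcols(gr)$alt <- as.character(alt)
  mcols(gr)$frequency <- as.numeric(frequency)
  mcols(gr)$source <- rep_len(source, n)
  new("FrequencyTable", variants = gr)
}

#' @rdname frequencyTable
#' @param table A [FrequencyTable-class].
#' @return `variants()` returns the underlying variant `GRanges`.
#' @export
variants <- function(table) table@variants

setMethod("show", "FrequencyTable", function(object) {
  v <- object@variants
  cat(sprintf("FrequencyTable: %d variant(s)", length(v)))
  if (length(v))
    cat(sprintf(" on %s, frequency %.4g-%.4g",
                paste(unique(as.character(seqnames(v))), collapse = ","),
                min(mcols(v)$frequency), max(mcols(v)$frequency)))
  cat("\n")
})

setMethod("length", "FrequencyTable", function(x) length(x@variants))

parseFrequency <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  val <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (any(is.na(val)))
    stop("format error: unparseable frequency value(s): ",
         paste(head(x[is.na(val)], 3L), collapse = ", "), call. = FALSE)
  val[pct] <- val[pct] / 100
  if (any(val < 0 | val > 1))
    stop("value error: frequency outside [0, 1]", call. = FALSE)
  val
}

#' Load population allele frequencies from VCF or TSV
#'
#' The VCF dialect takes `AF` from INFO, falling back to `AC/AN`;
#' multi-allelic records are split into one variant per alt allele.  The
#' TSV dialect has four columns -- contig, position, `REF>ALT` change, and
#' frequency -- where percent-formatted frequencies (`"21.94%"`) are
#' accepted and divided by 100.  Lines starting with `#` are ignored, as is
#' an optional header line.
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param source Provenance label stored with each variant (default: the
#'   dialect).
#' @return A [FrequencyTable-class].
#' @export
loadFrequencyTable <- function(path, dialect = c("tsv", "vcf"),
                               source = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(source)) source <- dialect
  if (dialect == "tsv") loadFrequencyTsv(path, source)
  else loadFrequencyVcf(path, source)
}

loadFrequencyTsv <- function(path, source) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(frequencyTable(source = source))
  fields <- strsplit(lines, "[\t ]+")
  ## tolerate a header row (non-numeric position column)
  if (suppressWarnings(is.na(as.integer(fields[[1L]][2L]))))
    fields <- fields[-1L]
  if (!length(fields))
    return(frequencyTable(source = source))
  bad <- vapply(fields, length, 0L) < 4L
  if (any(bad))
    stop("format error: TSV rows need 4 columns (contig, pos, ref>alt, frequency)",
         call. = FALSE)
  contig <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  change <- vapply(fields, `[[`, "", 3L)
  m <- regmatches(change, regexec("^([ACGTN]*)>([ACGTN]*)$", toupper(change)))
  if (any(vapply(m, length, 0L) != 3L))
    stop("format error: change column must be 'REF>ALT'", call. = FALSE)
  ref <- vapply(m, `[[`, "", 2L)
  alt <- vapply(m, `[[`, "", 3L)
  freq <- parseFrequency(vapply(fields, `[[`, "", 4L))
  frequencyTable(contig, pos, ref, alt, freq, source)
}

loadFrequencyVcf <- function(path, source) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- rowRanges(vcf)
  if (!length(rr)) return(frequencyTable(source = source))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  info <- VariantAnnotation::info(vcf)
  freqPerAlt <- function(field) {
    if (is.null(field)) return(NULL)
    unlist(lapply(seq_along(nAlt), function(i) {
      v <- as.numeric(unlist(field[i]))
      rep_len(v, nAlt[i])
    }))
  }
  af <- freqPerAlt(info$AF)
  if (is.null(af)) af <- rep(NA_real_, sum(nAlt))
  if (anyNA(af)) {
    ## per-record fallback to AC/AN for records without AF
    ac <- freqPerAlt(info$AC)
    an <- if (is.null(info$AN)) NULL else rep(as.numeric(info$AN), nAlt)
    if (!is.null(ac) && !is.null(an)) {
      fill <- is.na(af)
      af[fill] <- ac[fill] / an[fill]
    }
    if (anyNA(af))
      stop("format error: VCF needs AF, or AC and AN, in INFO", call. = FALSE)
  }
  idx <- rep(seq_along(rr), nAlt)
  ref <- rep(as.character(VariantAnnotation::ref(vcf)), nAlt)
  alt <- as.character(unlist(altList))
  if (any(is.na(af) | af < 0 | af > 1))
    stop("value error: VCF frequency outside [0, 1]", call. = FALSE)
  frequencyTable(as.character(seqnames(rr))[idx], start(rr)[idx],
                 ref, alt, af, source)
}

#' Write a frequency table as 4-column TSV
#'
#' Columns: contig, position, `REF>ALT`, frequency (fraction, full
#' precision, so that a reload reproduces frequencies exactly).
#'
#' @param table A [FrequencyTable-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(table, path) {
  v <- variants(table)
  lines <- sprintf("%s\t%d\t%s>%s\t%s",
                   as.character(seqnames(v)), start(v),
                   mcols(v)$ref, mcols(v)$alt,
                   format(mcols(v)$frequency, digits = 17, scientific = FALSE))
  writeLines(c("#contig\tpos\tchange\tfrequency", lines), path)
  invisible(path)
}

#' Frequent variants under a genomic footprint
#'
#' Returns population variants overlapping `footprint` whose frequency is
#' strictly greater than `threshold` (the ">1%" rule for allele-dropout
#' risk at primer sites), sorted by position.
#'
#' @param table A [FrequencyTable-class].
#' @param footprint A single-range [GenomicRanges::GRanges].
#' @param threshold Frequency threshold in \[0,1\] (strict `>`).
#' @return The matching variant `GRanges`.
#' @export
frequentVariantsInFootprint <- function(table, footprint, threshold = 0.01) {
  stopifnot(is(table, "FrequencyTable"), threshold >= 0, threshold <= 1)
  v <- variants(table)
  if (!length(v)) return(v)
  hit <- as.character(seqnames(v)) == as.character(seqnames(footprint))[1L] &
    start(v) <= end(footprint)[1L] & end(v) >= start(footprint)[1L] &
    mcols(v)$frequency > threshold
  v[hit][order(start(v[hit]))]
}

## Reduce a (pos, ref, alt) pair to a minimal representation by trimming
## the shared prefix/suffix, so VCF-anchored indels compare against
## PSV-style alleles.
trimAlleles <- function(pos, ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Annotate PSVs with gene-internal polymorphism frequencies
#'
#' For each PSV, looks up the population variant at its site whose alleles
#' match the PSV's gene/pseudogene alleles (position alone is not enough)
#' and records its frequency, or 0 when the site is not polymorphic in the
#' gene.  Indel matching compares 3'-normalized minimal alleles, so
#' VCF-anchored representations are accepted.
#'
#' @param psvs A PSV `GRanges` (see [psvRanges()]).
#' @param table A [FrequencyTable-class].
#' @return `psvs` with an added `frequency` metadata column.
#' @export
annotatePsvFrequencies <- function(psvs, table) {
  stopifnot(is(psvs, "GRanges"), is(table, "FrequencyTable"))
  v <- variants(table)
  freq <- numeric(length(psvs))
  if (length(v)) {
    vTrim <- lapply(seq_along(v), function(j)
      trimAlleles(start(v)[j], mcols(v)$ref[j], mcols(v)$alt[j]))
    for (i in seq_along(psvs)) {
      kind <- mcols(psvs)$kind[i]
      pGa <- mcols(psvs)$geneAllele[i]
      pPa <- mcols(psvs)$pseudoAllele[i]
      for (j in seq_along(v)) {
        if (as.character(seqnames(v))[j] != as.character(seqnames(psvs))[i])
          next
        tr <- vTrim[[j]]
        match <- switch(kind,
          substitution = tr$pos == start(psvs)[i] &&
            tr$ref == pGa && tr$alt == pPa,
          deletion = tr$alt == "" && tr$pos == start(psvs)[i] &&
            tr$ref == pGa,
          insertion = tr$ref == "" && (tr$pos - 1L) == start(psvs)[i] &&
            tr$alt == pPa,
          FALSE)
        if (isTRUE(match)) {
          freq[i] <- max(freq[i], mcols(v)$frequency[j])
        }
      }
    }
  }
  mcols(psvs)$frequency <- freq
  psvs
}

#' Write annotated PSVs as TSV or BED
#'
#' `writePsvTsv()` emits label, kind, position and gene-internal frequency
#' (0 when no `frequency` column is present); `writePsvBed()` emits 0-based
#' half-open BED intervals with the HGVS-style label as the name field.
#'
#' @param psvs A PSV `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePsvTsv <- function(psvs, path) {
  freq <- if ("frequency" %in% colnames(mcols(psvs)))
    mcols(psvs)$frequency else numeric(length(psvs))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s",
                   mcols(psvs)$label, mcols(psvs)$kind,
                   as.character(seqnames(psvs)), start(psvs), end(psvs),
                   format(freq, digits = 10, scientific = FALSE))
  writeLines(c("#label\tkind\tcontig\tstart\tend\tfrequency", lines), path)
  invisible(path)
}

#' @rdname writePsvTsv
#' @export
writePsvBed <- function(psvs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(seqnames(psvs)), start(psvs) - 1L, end(psvs),
                   mcols(psvs)$label)
  writeLines(lines, path)
  invisible(path)
}
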