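#' Read a single-record FASTA sequence
#'
#' Convenience reader for the gene / pseudogene inputs: the first record of
#' the file, uppercase-normalized, as a plain character string.
#'
#' @param path FASTA file.
#' @return Character string.
#' @export
readFastaSequence <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("no FASTA record in ", path, call. = FALSE)
  toupper(as.character(ss[[1L]]))
}

primerRow <- function(role, prm, report = NULL) {
  data.frame(
    role = role,
    sequence = prm@sequence,
    contig = as.character(seqnames(prm@footprint)),
    start = start(prm@footprint),
    end = end(prm@footprint),
    orientation = prm@orientation,
    tm = round(prm@tm, 2),
    gc = round(prm@gc, 3),
    specific = if (is.null(report)) NA else report@isSpecific,
    dropoutRisk = if (is.null(report)) NA else report@dropoutRisk,
    stringsAsFactors = FALSE)
}

#' Write the primers of an assay as TSV
#'
#' One row per primer: role, sequence, coordinates, Tm, GC and the
#' specificity / dropout flags from the assay's reports.
#'
#' @param assay An [AmpliconAssay-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePrimerTsv <- function(assay, path) {
  rows <- rbind(
    primerRow("forward", assay@forward, assay@reports$forward),
    primerRow("reverse", assay@reverse, assay@reports$reverse),
    if (!is.null(assay@sequencingPrimer))
      primerRow("sequencing", assay@sequencingPrimer,
                assay@reports$sequencing))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

assayToList <- function(assay) {
  prmList <- function(prm, report) list(
    sequence = prm@sequence,
    contig = as.character(seqnames(prm@footprint)),
    start = start(prm@footprint), end = end(prm@footprint),
    orientation = prm@orientation,
    tm = round(prm@tm, 2), gc = round(prm@gc, 3),
    specific = report@isSpecific,
    psvOffsets = report@psvOffsets,
    dropoutRisk = report@dropoutRisk)
  out <- list(
    amplicon = list(contig = as.character(seqnames(assay@amplicon)),
                    start = start(assay@amplicon),
                    end = end(assay@amplicon)),
    forward = prmList(assay@forward, assay@reports$forward),
    reverse = prmList(assay@reverse, assay@reports$reverse),
    psvsInAmplicon = mcols(assay@psvs)$label,
    panel = list(k = assay@panel@k,
                 sites = mcols(assay@panel@sites)$label,
                 frequencies = mcols(assay@panel@sites)$frequency,
                 warnings = assay@panel@warnings,
                 infeasible = assay@panel@infeasible))
  if (!is.null(assay@sequencingPrimer))
    out$sequencing <- prmList(assay@sequencingPrimer,
                              assay@reports$sequencing)
  out
}

#' Write a full assay report as JSON
#'
#' @param assay An [AmpliconAssay-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAssayJson <- function(assay, path) {
  jsonlite::write_json(assayToList(assay), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
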