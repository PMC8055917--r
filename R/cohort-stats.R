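#' Construct a GenotypeCount
#'
#' @param label Variant label.
#' @param homozygotes,heterozygotes Observed genotype counts.
#' @param nIndividuals Individuals tested.
#' @param reportedAlleles,reportedPercent Optional externally printed
#'   allele count / percentage, validated by [alleleFrequency()].
#' @return A [GenotypeCount-class].
#' @examples
#' genotypeCount("g.45069043G>A", 1, 13, 106)
#' @export
genotypeCount <- function(label, homozygotes, heterozygotes, nIndividuals,
                          reportedAlleles = NA_real_,
                          reportedPercent = NA_real_) {
  new("GenotypeCount", label = as.character(label),
      homozygotes = as.integer(homozygotes),
      heterozygotes = as.integer(heterozygotes),
      nIndividuals = as.integer(nIndividuals),
      reportedAlleles = as.numeric(reportedAlleles),
      reportedPercent = as.numeric(reportedPercent))
}

setMethod("show", "GenotypeCount", function(object) {
  cat(sprintf("GenotypeCount %s: %d hom + %d het of %d individuals\n",
              object@label, object@homozygotes, object@heterozygotes,
              object@nIndividuals))
})

#' Allele count and frequency from genotype counts
#'
#' Computes `alleleCount = 2 * homozygotes + heterozygotes` and the
#' percentage of the `2 * nIndividuals` tested alleles, reported to two
#' decimal places (the raw fraction is retained alongside).  When the
#' object carries an externally printed allele count or percentage that
#' disagrees with the computed value, a validation warning of class
#' `psvkitCountInconsistency` is raised -- the inconsistency is surfaced,
#' never silently repaired.
#'
#' @param gc A [GenotypeCount-class] with `nIndividuals > 0`.
#' @return A list: `label`, `alleleCount`, `allelesTested`, `percent`
#'   (2 dp) and `fraction` (unrounded).
#' @examples
#' alleleFrequency(genotypeCount("g.45069043G>A", 1, 13, 106))
#' @export
alleleFrequency <- function(gc) {
  stopifnot(is(gc, "GenotypeCount"))
  if (gc@nIndividuals <= 0L)
    stop("input error: nIndividuals must be > 0", call. = FALSE)
  ac <- 2L * gc@homozygotes + gc@heterozygotes
  nAll <- 2L * gc@nIndividuals
  frac <- ac / nAll
  if (!is.na(gc@reportedAlleles) && gc@reportedAlleles != ac)
    warning(warningCondition(
      sprintf("%s: computed allele count %d disagrees with reported %g (2*%d hom + %d het)",
              gc@label, ac, gc@reportedAlleles, gc@homozygotes,
              gc@heterozygotes),
      class = c("psvkitCountInconsistency", "warning", "condition")))
  if (!is.na(gc@reportedPercent) &&
      abs(gc@reportedPercent - round(100 * frac, 2)) > 0.005)
    warning(warningCondition(
      sprintf("%s: computed allele percentage %.2f disagrees with reported %.2f",
              gc@label, 100 * frac, gc@reportedPercent),
      class = c("psvkitCountInconsistency", "warning", "condition")))
  list(label = gc@label, alleleCount = ac, allelesTested = nAll,
       percent = round(100 * frac, 2), fraction = frac)
}

#' Pathogenic-allele spectrum from a patient roster
#'
#' Counts every pathogenic allele occurrence (a homozygote contributes 2,
#' each allele of a compound heterozygote 1, a single-heterozygote carrier
#' 1) and reports each variant's share of all pathogenic alleles, rounded
#' to the nearest integer percent (raw fractions retained).
#'
#' @param roster `data.frame` with columns `patient`, `family`, `allele1`,
#'   `allele2` (`NA` for a carrier with no second variant found).
#' @param variants Optional declared variant set; an allele label outside
#'   it is an input error.  Defaults to the labels present.
#' @return `data.frame` with one row per variant: `variant`, `count`,
#'   `percent` (integer), `fraction`; the attribute `"totalAlleles"` holds
#'   the pathogenic-allele total.
#' @export
alleleSpectrum <- function(roster, variants = NULL) {
  stopifnot(is.data.frame(roster), nrow(roster) > 0L,
            all(c("allele1", "allele2") %in% names(roster)))
  alleles <- c(as.character(roster$allele1), as.character(roster$allele2))
  alleles <- alleles[!is.na(alleles) & alleles != ""]
  if (is.null(variants)) variants <- unique(alleles)
  unknown <- setdiff(alleles, variants)
  if (length(unknown))
    stop("input error: unknown allele label(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  total <- length(alleles)
  counts <- table(factor(alleles, levels = variants))
  out <- data.frame(
    variant = names(counts),
    count = as.integer(counts),
    percent = as.integer(round(100 * as.integer(counts) / total)),
    fraction = as.integer(counts) / total,
    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totalAlleles") <- total
  out
}

formatRate <- function(pct) ifelse(pct < 1, round(pct, 2), round(pct, 1))

#' Per-arm detection rates for a screening cascade
#'
#' Computes `100 * nPositive / nTested` for each arm of a screening
#' workflow, printed to one decimal place (two when below 1%), plus
#' optional pooled rates over user-defined strata.
#'
#' @param counts `data.frame` with columns `arm`, `nTested`, `nPositive`
#'   (and optionally `definition`).
#' @param strata Optional named list; each element is a character vector of
#'   arm names pooled into one stratum.
#' @return `data.frame` with `arm`, `nTested`, `nPositive`, `rate` (raw
#'   percent) and `percent` (printed precision); pooled strata are appended
#'   as extra rows.
#' @examples
#' cascadeSummary(data.frame(arm = "fragment", nTested = 931, nPositive = 17))
#' @export
cascadeSummary <- function(counts, strata = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("arm", "nTested", "nPositive") %in% names(counts)))
  if (any(counts$nTested <= 0L))
    stop("undefined-rate error: nTested must be > 0 for every arm",
         call. = FALSE)
  if (any(counts$nPositive < 0L | counts$nPositive > counts$nTested))
    stop("input error: nPositive must lie in [0, nTested]", call. = FALSE)
  out <- data.frame(arm = as.character(counts$arm),
                    nTested = as.integer(counts$nTested),
                    nPositive = as.integer(counts$nPositive),
                    stringsAsFactors = FALSE)
  if (!is.null(strata)) {
    for (nm in names(strata)) {
      sel <- out$arm %in% strata[[nm]]
      if (!any(sel))
        stop("input error: stratum '", nm, "' matches no arm", call. = FALSE)
      out <- rbind(out, data.frame(arm = nm,
                                   nTested = sum(out$nTested[sel]),
                                   nPositive = sum(out$nPositive[sel]),
                                   stringsAsFactors = FALSE))
    }
  }
  out$rate <- 100 * out$nPositive / out$nTested
  out$percent <- formatRate(out$rate)
  out
}

#' Write / read a cascade report as JSON
#'
#' Serialization round-trips exactly: re-reading reproduces identical
#' rates.
#'
#' @param summary A `data.frame` from [cascadeSummary()].
#' @param path JSON file path.
#' @return `writeCascadeJson()`: `path`, invisibly; `readCascadeJson()`:
#'   the `data.frame`.
#' @export
writeCascadeJson <- function(summary, path) {
  jsonlite::write_json(summary, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeCascadeJson
#' @export
readCascadeJson <- function(path) {
  out <- jsonlite::fromJSON(path)
  out$nTested <- as.integer(out$nTested)
  out$nPositive <- as.integer(out$nPositive)
  out
}

#' Call a fragment-analysis genotype from peak lengths
#'
#' Capillary-electrophoresis sizing of a fluorescent PCR product around a
#' small deletion: a wild-type peak at `wtLength` and a deletion peak at
#' `wtLength - shift`.  Peaks are matched within `tolerance` bases
#' (default 0.4, typical capillary sizing precision).
#'
#' @param peaks Numeric peak lengths (bases); may be empty.
#' @param wtLength Expected wild-type fragment length.
#' @param shift Length shift of the deletion allele (1 for a single-base
#'   deletion); must be >= 1.
#' @param tolerance Matching tolerance in bases.
#' @return `"hom_wt"`, `"het"`, `"hom_del"` or `"no_call"`.
#' @examples
#' fragmentGenotype(c(199.1, 200.0), 200, 1)  # "het"
#' @export
fragmentGenotype <- function(peaks, wtLength, shift = 1, tolerance = 0.4) {
  stopifnot(shift >= 1, tolerance >= 0)
  if (!length(peaks)) return("no_call")
  isWt <- abs(peaks - wtLength) <= tolerance
  isDel <- abs(peaks - (wtLength - shift)) <= tolerance
  if (any(!isWt & !isDel)) return("no_call")
  hasWt <- any(isWt)
  hasDel <- any(isDel)
  if (hasWt && hasDel) "het" else if (hasWt) "hom_wt" else "hom_del"
}

#' Read / write cohort tables
#'
#' `readGenotypeCounts()` reads a TSV with columns `label`, `hom`, `het`,
#' `n` (optional `reportedAlleles`, `reportedPercent`) into a list of
#' [GenotypeCount-class]; `readRoster()` reads a TSV with columns
#' `patient`, `family`, `allele1`, `allele2` (empty/`NA` second allele
#' allowed).
#'
#' @param path TSV file path.
#' @return A list of `GenotypeCount`, or a roster `data.frame`.
#' @export
readGenotypeCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    genotypeCount(df$label[i], df$hom[i], df$het[i], df$n[i],
                  if ("reportedAlleles" %in% names(df))
                    df$reportedAlleles[i] else NA_real_,
                  if ("reportedPercent" %in% names(df))
                    df$reportedPercent[i] else NA_real_))
}

#' @rdname readGenotypeCounts
#' @export
readRoster <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("patient", "family", "allele1", "allele2") %in% names(df)))
  df
}
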