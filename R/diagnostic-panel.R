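#' Select a diagnostic SNP panel inside an amplicon
#'
#' Chooses the `k` PSV sites with the lowest gene-internal polymorphism
#' frequency (ties broken by position) among the in-amplicon PSVs, after
#' excluding the assay's target variant site.  Reading these sites from a
#' Sanger trace verifies that only the gene -- not the pseudogene -- was
#' amplified; sites that are themselves polymorphic in the gene can be
#' confusing, so a selected site with frequency above `maxFreqWarn` carries
#' a warning but remains eligible.  The objective is lexicographic
#' (minimize the maximum frequency, then the sum), which the sort-and-take
#' selection attains deterministically.
#'
#' @param annotatedPsvs PSV `GRanges` carrying a `frequency` metadata
#'   column (see [annotatePsvFrequencies()]).
#' @param amplicon Single-range [GenomicRanges::GRanges].
#' @param k Panel size (default 3).
#' @param exclude Labels (or a PSV `GRanges`) of sites to exclude,
#'   typically the assay's target variant.
#' @param maxFreqWarn Warn when a selected site's gene-internal frequency
#'   exceeds this fraction (default 0.05).
#' @return A [DiagnosticPanel-class]; when fewer than `k` sites are
#'   eligible the panel is partial and flagged infeasible.
#' @export
selectPanel <- function(annotatedPsvs, amplicon, k = 3L,
                        exclude = character(0), maxFreqWarn = 0.05) {
  stopifnot(is(annotatedPsvs, "GRanges"), k >= 1L)
  if (!"frequency" %in% colnames(mcols(annotatedPsvs)))
    stop("annotatedPsvs must carry a 'frequency' metadata column; see annotatePsvFrequencies()",
         call. = FALSE)
  k <- as.integer(k)
  if (is(exclude, "GRanges")) exclude <- mcols(exclude)$label
  sites <- psvsInInterval(annotatedPsvs, amplicon)
  sites <- sites[!(mcols(sites)$label %in% exclude)]
  o <- order(mcols(sites)$frequency, start(sites))
  sites <- sites[o]
  warnings <- character(0)
  infeasible <- FALSE
  if (length(sites) < k) {
    infeasible <- TRUE
    warnings <- c(warnings, sprintf(
      "only %d eligible site(s) for a panel of %d", length(sites), k))
  } else {
    sites <- sites[seq_len(k)]
  }
  hot <- mcols(sites)$frequency > maxFreqWarn
  if (any(hot))
    warnings <- c(warnings, sprintf(
      "site %s is polymorphic in the gene (frequency %.3g > %.3g) and may be confusing",
      mcols(sites)$label[hot], mcols(sites)$frequency[hot], maxFreqWarn))
  new("DiagnosticPanel", sites = sites, k = k,
      warnings = warnings, infeasible = infeasible)
}

#' @rdname selectPanel
#' @param panel A [DiagnosticPanel-class].
#' @return `panelSites()` returns the panel's PSV `GRanges`;
#'   `panelLabels()` the site labels.
#' @export
panelSites <- function(panel) panel@sites

#' @rdname selectPanel
#' @export
panelLabels <- function(panel) mcols(panel@sites)$label

setMethod("show", "DiagnosticPanel", function(object) {
  cat(sprintf("DiagnosticPanel (k = %d%s):\n", object@k,
              if (object@infeasible) ", INFEASIBLE" else ""))
  s <- object@sites
  for (i in seq_along(s))
    cat(sprintf("  %s  (gene-internal frequency %.4g)\n",
                mcols(s)$label[i], mcols(s)$frequency[i]))
  for (w in object@warnings) cat("  warning: ", w, "\n", sep = "")
})

.traceGenotypes <- c("gene_allele_only", "heterozygous", "pseudo_allele_only")

#' Classify a trace observation against a diagnostic panel
#'
#' Given the genotype observed at every panel site in a Sanger trace,
#' decides whether the amplification was gene-specific.  A pseudogene
#' allele at a site that is never polymorphic in the gene (frequency 0)
#' can only come from co-amplified pseudogene template; a pseudogene
#' allele only at sites that are genuinely polymorphic in the gene could
#' be a real gene polymorphism, so the call is inconclusive rather than
#' suspected.
#'
#' @param panel A [DiagnosticPanel-class].
#' @param obs Named character vector (or list), one entry per panel site
#'   label, values in `"gene_allele_only"`, `"heterozygous"`,
#'   `"pseudo_allele_only"`.
#' @return One of `"gene_specific"`, `"co_amplification_suspected"`,
#'   `"inconclusive"`.
#' @export
classifyTrace <- function(panel, obs) {
  stopifnot(is(panel, "DiagnosticPanel"))
  obs <- unlist(obs)
  labels <- mcols(panel@sites)$label
  missing <- setdiff(labels, names(obs))
  if (length(missing))
    stop("input error: missing observation for panel site(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  obs <- obs[labels]
  if (!all(obs %in% .traceGenotypes))
    stop("input error: observations must be one of: ",
         paste(.traceGenotypes, collapse = ", "), call. = FALSE)
  freq <- mcols(panel@sites)$frequency
  pseudoSignal <- obs != "gene_allele_only"
  if (any(pseudoSignal & freq == 0)) return("co_amplification_suspected")
  if (!any(pseudoSignal)) return("gene_specific")
  "inconclusive"
}
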