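#' Primer binding model for in-silico PCR
#'
#' A primer is considered to bind (and extend) when it aligns to the
#' template with at most `maxMismatch` substitutions overall and at most
#' `max3Mismatch` of them inside the 3'-terminal `window3` bases -- the
#' region where a mismatch most effectively blocks extension.  No indels
#' are allowed in the binding site.
#'
#' @param maxMismatch Maximum total mismatches (default 2).
#' @param max3Mismatch Maximum mismatches in the 3'-terminal window
#'   (default 0).
#' @param window3 3'-terminal window in bases (default 3).
#' @param maxProduct Maximum predicted product length (default 5000).
#' @return A list of binding-model parameters.
#' @export
bindingModel <- function(maxMismatch = 2L, max3Mismatch = 0L,
                         window3 = 3L, maxProduct = 5000L) {
  list(maxMismatch = as.integer(maxMismatch),
       max3Mismatch = as.integer(max3Mismatch),
       window3 = as.integer(window3),
       maxProduct = as.integer(maxProduct))
}

## All binding sites of `seq` (5'->3') on a template.  strand "+" means
## the primer anneals so that extension runs rightward (primer equals the
## template top strand; 3' end at the site's right edge); strand "-" means
## extension runs leftward (primer equals the reverse complement; 3' end at
## the site's left edge).  Mismatches in the 3' window are counted on the
## primer's own 3'-terminal bases.
primerBindingSites <- function(seq, template, model) {
  out <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") seq else revComp(seq)
    hits <- Biostrings::matchPattern(query, template,
                                     max.mismatch = model$maxMismatch,
                                     with.indels = FALSE)
    if (!length(hits)) next
    qch <- strsplit(query, "")[[1L]]
    n <- length(qch)
    for (i in seq_along(hits)) {
      s <- start(hits)[i]
      tch <- strsplit(as.character(hits[[i]]), "")[[1L]]
      mis <- qch != tch
      total <- sum(mis)
      if (total > model$maxMismatch) next
      w <- min(model$window3, n)
      mis3 <- if (strand == "+") sum(mis[(n - w + 1L):n]) else sum(mis[1L:w])
      if (mis3 > model$max3Mismatch) next
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, start = s, end = s + n - 1L,
        mismatches = total, mismatches3 = mis3,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      mismatches3 = integer(0)))
  do.call(rbind, out)
}

#' Predict PCR products by in-silico PCR
#'
#' Locates every binding site of both primers on both strands of the
#' template under the [bindingModel()] and emits a product for every pair
#' of sites in convergent orientation (a plus-strand site upstream of a
#' minus-strand site) within the product-length cap.  A primer pair that
#' binds the pseudogene as well as the gene will therefore report products
#' on both templates (co-amplification).
#'
#' @param forward,reverse [Primer-class] objects or plain 5'->3' sequences.
#' @param template Template sequence (character or `DNAString`).
#' @param model Binding model from [bindingModel()].
#' @return A `data.frame` with one row per predicted product: `start`,
#'   `end`, `length`, which primer bound each side (`plusPrimer`,
#'   `minusPrimer`) and per-primer total and 3'-window mismatch counts.
#'   Zero rows when no product is predicted.
#' @examples
#' inSilicoPcr("ACGTACGTACGTACGTAC", "TTGCAGGCATTGCAGGCA",
#'             paste0("ACGTACGTACGTACGTAC", strrep("A", 40),
#'                    "TGCCTGCAATGCCTGCAA"))
#' @export
inSilicoPcr <- function(forward, reverse, template, model = bindingModel()) {
  fwdSeq <- if (is(forward, "Primer")) forward@sequence
            else checkDna(forward, "forward primer", allowN = FALSE)
  revSeq <- if (is(reverse, "Primer")) reverse@sequence
            else checkDna(reverse, "reverse primer", allowN = FALSE)
  template <- checkDna(template, "template")

  tagSites <- function(df, name) {
    df$primer <- rep_len(name, nrow(df))
    df
  }
  sites <- rbind(
    tagSites(primerBindingSites(fwdSeq, template, model), "forward"),
    tagSites(primerBindingSites(revSeq, template, model), "reverse"))
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  products <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (minus$start[j] < plus$start[i]) next
      len <- minus$end[j] - plus$start[i] + 1L
      if (len > model$maxProduct) next
      products[[length(products) + 1L]] <- data.frame(
        start = plus$start[i], end = minus$end[j], length = len,
        plusPrimer = plus$primer[i], minusPrimer = minus$primer[j],
        plusMismatches = plus$mismatches[i],
        minusMismatches = minus$mismatches[j],
        plusMismatches3 = plus$mismatches3[i],
        minusMismatches3 = minus$mismatches3[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(products))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), plusPrimer = character(0),
                      minusPrimer = character(0),
                      plusMismatches = integer(0),
                      minusMismatches = integer(0),
                      plusMismatches3 = integer(0),
                      minusMismatches3 = integer(0)))
  res <- do.call(rbind, products)
  res[order(res$start, res$end), , drop = FALSE]
}
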