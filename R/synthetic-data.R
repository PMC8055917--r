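## Seeded synthetic-data generators.  All randomness goes through
## withr::with_seed(seed, ...): the same seed reproduces identical output
## and the caller's RNG state is left untouched.

.bases <- c("A", "C", "G", "T")

## k positions in [margin, L - margin], pairwise >= sep apart.
spacedPositions <- function(L, k, sep, margin) {
  if (k == 0L) return(integer(0))
  span <- L - 2L * margin
  avail <- span - (k - 1L) * sep
  if (avail < k)
    stop("parameter error: cannot place ", k,
         " edits with separation ", sep, " in length ", L, call. = FALSE)
  sort(sample.int(avail, k)) + (seq_len(k) - 1L) * sep + margin
}

#' Simulate a gene/pseudogene pair with known differences
#'
#' Generates a random gene and derives the pseudogene by planting
#' substitutions and short indels.  Defaults mirror a realistic
#' high-homology pair: 2320 bp with 22 substitutions and 3 single-base
#' indels (about 99% identity with three gaps).  Edits are separated by at
#' least `max(2 * maxIndel, 6)` bases so the planted truth is
#' alignment-unambiguous -- a simulator constraint, not a biological claim.
#' Truth PSVs are recorded in 3'-normalized (HGVS) form.
#'
#' @param length Gene length in bases.
#' @param nSubs,nIndels Numbers of substitutions and indels; must satisfy
#'   `nSubs + nIndels * maxIndel < length / 10`.
#' @param maxIndel Maximum indel length (bases).
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @param contig Contig name used for coordinates.
#' @param positions Optional explicit edit positions (length
#'   `nSubs + nIndels`; the first `nSubs` are substitution sites); must
#'   respect the separation constraint.
#' @param targetDel When `TRUE`, one indel is forced to be a single-base
#'   deletion (frameshift-style: the pseudogene carries the deletion) at
#'   the edit position nearest the sequence midpoint, and its label is
#'   recorded as `truth$targetLabel`.
#' @return A list: `geneSeq`, `pseudoSeq`, and `truth` (a list with
#'   `seed`, the planted PSV `GRanges` `psvs`, and optionally
#'   `targetLabel`).
#' @examples
#' sim <- simulateParalogPair(600, nSubs = 6, nIndels = 1, seed = 1)
#' identityStats(alignParalogs(sim$geneSeq, sim$pseudoSeq))
#' @export
simulateParalogPair <- function(length = 2320L, nSubs = 22L, nIndels = 3L,
                                maxIndel = 1L, seed, contig = "gene",
                                positions = NULL, targetDel = FALSE) {
  length <- as.integer(length); nSubs <- as.integer(nSubs)
  nIndels <- as.integer(nIndels); maxIndel <- as.integer(maxIndel)
  if (nSubs + nIndels * maxIndel >= length / 10)
    stop("parameter error: too many edits for the sequence length",
         call. = FALSE)
  sep <- max(2L * maxIndel, 6L)
  k <- nSubs + nIndels
  withr::with_seed(seed, {
    geneChars <- sample(.bases, length, replace = TRUE)
    if (is.null(positions)) {
      pos <- spacedPositions(length, k, sep, margin = 25L)
      ## randomize which spaced slots carry indels
      idx <- if (k > 0L) sample.int(k) else integer(0)
      subPos <- sort(pos[idx[seq_len(nSubs)]])
      indelPos <- sort(pos[idx[nSubs + seq_len(nIndels)]])
    } else {
      stopifnot(length(positions) == k)
      if (k > 1L && min(diff(sort(positions))) < sep)
        stop("parameter error: explicit positions violate the separation constraint",
             call. = FALSE)
      subPos <- sort(positions[seq_len(nSubs)])
      indelPos <- sort(positions[nSubs + seq_len(nIndels)])
    }
    edits <- list()
    for (p in subPos) {
      alt <- sample(setdiff(.bases, geneChars[p]), 1L)
      edits[[length(edits) + 1L]] <- list(kind = "substitution", pos = p,
                                          len = 1L, alt = alt)
    }
    forcedTarget <- NA_integer_
    if (isTRUE(targetDel) && nIndels > 0L)
      forcedTarget <- indelPos[which.min(abs(indelPos - length / 2))]
    for (p in indelPos) {
      if (!is.na(forcedTarget) && p == forcedTarget) {
        kind <- "deletion"; len <- 1L
      } else {
        kind <- sample(c("deletion", "insertion"), 1L)
        len <- sample.int(maxIndel, 1L)
      }
      ins <- if (kind == "insertion")
        paste(sample(.bases, len, replace = TRUE), collapse = "") else ""
      edits[[length(edits) + 1L]] <- list(kind = kind, pos = p, len = len,
                                          alt = ins)
    }
    ## apply edits right-to-left so earlier positions stay valid
    pseudo <- geneChars
    ord <- order(vapply(edits, `[[`, 0L, "pos"), decreasing = TRUE)
    for (e in edits[ord]) {
      if (e$kind == "substitution") {
        pseudo[e$pos] <- e$alt
      } else if (e$kind == "deletion") {
        pseudo <- pseudo[-(e$pos:(e$pos + e$len - 1L))]
      } else {
        pseudo <- append(pseudo, strsplit(e$alt, "")[[1L]], after = e$pos)
      }
    }
    ## truth PSVs, 3'-normalized against the gene
    truthList <- lapply(edits, function(e) {
      if (e$kind == "substitution") {
        list(kind = "substitution", s = e$pos, e = e$pos,
             ga = geneChars[e$pos], pa = e$alt)
      } else if (e$kind == "deletion") {
        del <- paste(geneChars[e$pos:(e$pos + e$len - 1L)], collapse = "")
        sh <- shift3Prime(geneChars, "deletion", e$pos, del)
        list(kind = "deletion", s = sh$pos,
             e = sh$pos + nchar(sh$allele) - 1L, ga = sh$allele, pa = "")
      } else {
        sh <- shift3Prime(geneChars, "insertion", e$pos, e$alt)
        list(kind = "insertion", s = sh$pos, e = sh$pos, ga = "",
             pa = sh$allele)
      }
    })
    psvs <- if (length(truthList))
      psvRanges(contig,
                start = vapply(truthList, `[[`, 0L, "s"),
                end = vapply(truthList, `[[`, 0L, "e"),
                kind = vapply(truthList, `[[`, "", "kind"),
                geneAllele = vapply(truthList, `[[`, "", "ga"),
                pseudoAllele = vapply(truthList, `[[`, "", "pa"))
    else
      psvRanges(contig, integer(0), integer(0), character(0),
                character(0), character(0))
    truth <- list(seed = seed, psvs = psvs)
    if (!is.na(forcedTarget)) {
      tIdx <- which(vapply(truthList, `[[`, "", "kind") == "deletion" &
                      vapply(truthList, function(t) t$s, 0L) ==
                      shift3Prime(geneChars, "deletion", forcedTarget,
                                  geneChars[forcedTarget])$pos)
      if (length(tIdx))
        truth$targetLabel <- mcols(psvs)$label[
          match(truthList[[tIdx[1L]]]$s, start(psvs))]
    }
    list(geneSeq = paste(geneChars, collapse = ""),
         pseudoSeq = paste(pseudo, collapse = ""),
         truth = truth)
  })
}

#' Simulate a population SNP table with stated frequencies
#'
#' Places SNPs with exactly the requested frequencies at the requested (or
#' random) positions, optionally avoiding planted PSV sites.
#'
#' @param geneSeq Gene sequence (used for reference alleles); or give
#'   `geneLength` for random reference alleles.
#' @param freqs Allele frequencies (fractions in \[0,1\]), one SNP each.
#' @param positions Optional explicit positions.
#' @param seed Integer seed.
#' @param geneLength Gene length when `geneSeq` is not supplied.
#' @param contig Contig name.
#' @param avoid Optional `GRanges` (e.g. planted PSVs) whose positions are
#'   excluded; an explicit position colliding with `avoid` is a parameter
#'   error unless `allowCollision = TRUE` (a PSV site that is also a
#'   gene-internal polymorphism is a legitimate scenario).
#' @param allowCollision Permit explicit positions inside `avoid`.
#' @return A [FrequencyTable-class]; the attribute `"truth"` records seed,
#'   positions and frequencies.
#' @export
simulateSnpTable <- function(geneSeq = NULL, freqs, positions = NULL, seed,
                             geneLength = NULL, contig = "gene",
                             avoid = NULL, allowCollision = FALSE) {
  if (any(freqs < 0 | freqs > 1))
    stop("parameter error: frequencies must lie in [0, 1]", call. = FALSE)
  if (is.null(geneSeq) && is.null(geneLength))
    stop("supply geneSeq or geneLength", call. = FALSE)
  L <- if (is.null(geneSeq)) as.integer(geneLength) else nchar(geneSeq)
  avoidPos <- if (is.null(avoid)) integer(0)
              else unlist(lapply(seq_along(avoid),
                                 function(i) start(avoid)[i]:end(avoid)[i]))
  withr::with_seed(seed, {
    n <- length(freqs)
    if (is.null(positions)) {
      pool <- setdiff(seq_len(L), avoidPos)
      if (length(pool) < n)
        stop("parameter error: not enough non-PSV positions", call. = FALSE)
      positions <- sort(sample(pool, n))
    } else {
      stopifnot(length(positions) == n)
      if (!allowCollision && any(positions %in% avoidPos))
        stop("parameter error: requested SNP position collides with a planted PSV",
             call. = FALSE)
    }
    ref <- if (is.null(geneSeq))
      sample(.bases, n, replace = TRUE)
    else
      vapply(positions, function(p) substr(geneSeq, p, p), "")
    alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1L), "",
                  USE.NAMES = FALSE)
    ft <- frequencyTable(contig, positions, ref, alt, freqs,
                         source = "simulated")
    attr(ft, "truth") <- list(seed = seed, positions = positions,
                              freqs = freqs)
    ft
  })
}

#' Simulate cohort genotype counts under Hardy-Weinberg equilibrium
#'
#' Draws `n` individuals i.i.d. with genotype probabilities `p^2`
#' (homozygous), `2p(1-p)` (heterozygous), `(1-p)^2` (wild type).
#'
#' @param p True allele frequency in \[0,1\].
#' @param n Individuals.
#' @param seed Integer seed.
#' @param label Variant label stored on the result.
#' @return A [GenotypeCount-class]; the attribute `"truth"` records `p`
#'   and the seed.
#' @examples
#' simulateCohort(0.0896, 931, seed = 7)
#' @export
simulateCohort <- function(p, n, seed, label = "simulated") {
  stopifnot(p >= 0, p <= 1, n >= 1)
  withr::with_seed(seed, {
    draw <- rmultinom(1L, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
    gc <- genotypeCount(label, draw[1L], draw[2L], n)
    attr(gc, "truth") <- list(p = p, seed = seed)
    gc
  })
}

#' Simulate fragment-analysis peak lengths
#'
#' Peaks at the expected fragment lengths for the genotype, plus Gaussian
#' capillary sizing noise.
#'
#' @param genotype `"hom_wt"`, `"het"` or `"hom_del"`.
#' @param wtLength Wild-type fragment length (bases).
#' @param shift Deletion length shift.
#' @param sizingNoiseSd Standard deviation of sizing noise (bases).
#' @param seed Integer seed.
#' @return Numeric peak lengths; the attribute `"truth"` records the
#'   genotype and seed.
#' @export
simulateFragmentPeaks <- function(genotype = c("hom_wt", "het", "hom_del"),
                                  wtLength = 200, shift = 1,
                                  sizingNoiseSd = 0, seed) {
  genotype <- match.arg(genotype)
  stopifnot(sizingNoiseSd >= 0)
  expected <- switch(genotype,
                     hom_wt = wtLength,
                     het = c(wtLength - shift, wtLength),
                     hom_del = wtLength - shift)
  withr::with_seed(seed, {
    peaks <- expected + rnorm(length(expected), 0, sizingNoiseSd)
    attr(peaks, "truth") <- list(genotype = genotype, seed = seed)
    peaks
  })
}
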