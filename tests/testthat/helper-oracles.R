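## Independent oracles used to validate the package's implementations.
## These deliberately share no code with the package internals.

## Exhaustive Gotoh dynamic-programming score for a global alignment with
## affine gaps: a gap of length L costs gapOpening + L * gapExtension.
## N scores as a mismatch against everything, including N.
gotohScore <- function(x, y, match = 2, mismatch = -3,
                       gapOpening = 5, gapExtension = 2) {
  xs <- strsplit(x, "")[[1L]]
  ys <- strsplit(y, "")[[1L]]
  n <- length(xs); m <- length(ys)
  sub <- function(a, b) if (a == b && a != "N") match else mismatch
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in y (x base over gap)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in x
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(gapOpening + i * gapExtension)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(gapOpening + j * gapExtension)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- sub(xs[i], ys[j]) +
        max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(
        M[i, j + 1L] - gapOpening - gapExtension,
        X[i, j + 1L] - gapExtension,
        Y[i, j + 1L] - gapOpening - gapExtension)
      Y[i + 1L, j + 1L] <- max(
        M[i + 1L, j] - gapOpening - gapExtension,
        Y[i + 1L, j] - gapExtension,
        X[i + 1L, j] - gapOpening - gapExtension)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## Brute-force in-silico PCR: exhaustive scan over every offset of both
## primers on both strands, then every convergent site pair.
bruteRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

brutePcrProducts <- function(fwd, rev, template, maxMismatch = 2L,
                             max3Mismatch = 0L, window3 = 3L,
                             maxProduct = 5000L) {
  tch <- strsplit(template, "")[[1L]]
  L <- length(tch)
  siteScan <- function(primerSeq, strand) {
    query <- if (strand == "+") primerSeq else bruteRevComp(primerSeq)
    qch <- strsplit(query, "")[[1L]]
    n <- length(qch)
    out <- list()
    for (s in seq_len(L - n + 1L)) {
      mis <- qch != tch[s:(s + n - 1L)]
      if (sum(mis) > maxMismatch) next
      w <- min(window3, n)
      mis3 <- if (strand == "+") sum(mis[(n - w + 1L):n]) else sum(mis[1L:w])
      if (mis3 > max3Mismatch) next
      out[[length(out) + 1L]] <- c(start = s, end = s + n - 1L)
    }
    out
  }
  plus <- c(lapply(siteScan(fwd, "+"), c, primer = 1L),
            lapply(siteScan(rev, "+"), c, primer = 2L))
  minus <- c(lapply(siteScan(fwd, "-"), c, primer = 1L),
             lapply(siteScan(rev, "-"), c, primer = 2L))
  prods <- list()
  for (p in plus) {
    for (q in minus) {
      if (q[["start"]] < p[["start"]]) next
      len <- q[["end"]] - p[["start"]] + 1L
      if (len > maxProduct) next
      prods[[length(prods) + 1L]] <- c(start = p[["start"]],
                                       end = q[["end"]], length = len)
    }
  }
  if (!length(prods))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  df <- unique(as.data.frame(do.call(rbind, prods)))
  df[order(df$start, df$end), , drop = FALSE]
}

## Brute-force diagnostic-panel objective: best (max frequency, then sum)
## over all k-subsets of candidate sites.
brutePanelObjective <- function(freqs, k) {
  best <- NULL
  for (idx in utils::combn(length(freqs), k, simplify = FALSE)) {
    obj <- c(max(freqs[idx]), sum(freqs[idx]))
    if (is.null(best) || obj[1L] < best[1L] ||
        (obj[1L] == best[1L] && obj[2L] < best[2L]))
      best <- obj
  }
  best
}

## Brute force the 3'-most placement of a single-base deletion: every
## position whose removal from `gene` yields `pseudo`, take the largest.
bruteDeletion3Prime <- function(gene, pseudo) {
  hits <- integer(0)
  for (i in seq_len(nchar(gene))) {
    cand <- paste0(substr(gene, 1L, i - 1L), substr(gene, i + 1L, nchar(gene)))
    if (cand == pseudo) hits <- c(hits, i)
  }
  max(hits)
}
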