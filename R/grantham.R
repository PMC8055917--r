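## Grantham (1974) physiochemical distance matrix, scale 0-215, built from
## the published upper triangle (amino-acid order as in the original table).

.granthamOrder <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                    "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.granthamUpper <- c(
  ## Ser vs R  L    P   T   A    V   G    I    F    Y    C    H   Q   N    K    D   E    M    W
  110, 145, 74, 58, 99, 124, 56, 142, 155, 144, 112, 89, 68, 46, 121, 65, 80, 135, 177,
  ## Arg
  102, 103, 71, 112, 96, 125, 97, 97, 77, 180, 29, 43, 86, 26, 96, 54, 91, 101,
  ## Leu
  98, 92, 96, 32, 138, 5, 22, 36, 198, 99, 113, 153, 107, 172, 138, 15, 61,
  ## Pro
  38, 27, 68, 42, 95, 114, 110, 169, 77, 76, 91, 103, 108, 93, 87, 147,
  ## Thr
  58, 69, 59, 89, 103, 92, 149, 47, 42, 65, 78, 85, 65, 81, 128,
  ## Ala
  64, 60, 94, 113, 112, 195, 86, 91, 111, 106, 126, 107, 84, 148,
  ## Val
  109, 29, 50, 55, 192, 84, 96, 133, 97, 152, 121, 21, 88,
  ## Gly
  135, 153, 147, 159, 98, 87, 80, 127, 94, 98, 127, 184,
  ## Ile
  21, 33, 198, 94, 109, 149, 102, 168, 134, 10, 61,
  ## Phe
  22, 205, 100, 116, 158, 102, 177, 140, 28, 40,
  ## Tyr
  194, 83, 99, 143, 85, 160, 122, 36, 37,
  ## Cys
  174, 154, 139, 202, 154, 170, 196, 215,
  ## His
  24, 68, 32, 81, 40, 87, 115,
  ## Gln
  46, 53, 61, 29, 101, 130,
  ## Asn
  94, 23, 42, 142, 174,
  ## Lys
  101, 56, 95, 110,
  ## Asp
  45, 160, 181,
  ## Glu
  126, 152,
  ## Met
  67
)

.granthamMatrix <- local({
  n <- length(.granthamOrder)
  m <- matrix(0, n, n, dimnames = list(.granthamOrder, .granthamOrder))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      m[i, j] <- .granthamUpper[k]
      m[j, i] <- .granthamUpper[k]
    }
  }
  m
})

.aaThreeToOne <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

normalizeAa <- function(x) {
  x <- as.character(x)
  vapply(x, function(a) {
    if (nchar(a) == 1L) {
      a <- toupper(a)
      if (!a %in% .granthamOrder)
        stop("input error: unknown amino-acid code: ", a, call. = FALSE)
      return(a)
    }
    key <- paste0(toupper(substr(a, 1L, 1L)), tolower(substr(a, 2L, 3L)))
    if (!key %in% names(.aaThreeToOne))
      stop("input error: unknown amino-acid code: ", a, call. = FALSE)
    unname(.aaThreeToOne[key])
  }, "", USE.NAMES = FALSE)
}

#' Grantham physiochemical distance between amino acids
#'
#' Distance on the published 0-215 scale (Grantham 1974), combining
#' composition, polarity and molecular volume; symmetric, with 0 for
#' identical residues.  One- and three-letter codes are accepted and may be
#' mixed; inputs are vectorized pairwise.
#'
#' @param aaFrom,aaTo Amino-acid codes (`"S"`, `"Ser"`, ...).
#' @return Numeric distance(s).
#' @examples
#' granthamDistance("Ser", "Leu")  # 145
#' granthamDistance("G", "D")      # 94
#' @export
granthamDistance <- function(aaFrom, aaTo) {
  a <- normalizeAa(aaFrom)
  b <- normalizeAa(aaTo)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  .granthamMatrix[cbind(a, b)]
}

#' @rdname granthamDistance
#' @return `granthamMatrix()` returns the full symmetric 20x20 matrix
#'   (one-letter row/column names).
#' @export
granthamMatrix <- function() .granthamMatrix
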