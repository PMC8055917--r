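## Nearest-neighbor parameters: SantaLucia (1998) unified set.
## dH in kcal/mol, dS in cal/(mol K), for 5'->3' dinucleotide steps.
.nnDH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nnDS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature
#'
#' Two standard predictions: the Wallace rule, `Tm = 2(A+T) + 4(G+C)`,
#' and unified nearest-neighbor thermodynamics (SantaLucia 1998) with the
#' entropic salt correction `dS + 0.368 (L-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`.  Both are deterministic
#' functions of the sequence and the configured conditions.
#'
#' @param seq Primer sequence, length >= 8, alphabet \{A,C,G,T\}
#'   (ambiguity codes are rejected).
#' @param method `"wallace"` or `"nearest_neighbor"`.
#' @param primerConc Total primer concentration in mol/L (default 500 nM,
#'   a typical PCR condition).
#' @param Na Monovalent cation concentration in mol/L (default 50 mM).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("GCGCGCGC", method = "wallace")  # 32
#' @export
meltingTemperature <- function(seq,
                               method = c("nearest_neighbor", "wallace"),
                               primerConc = 5e-7, Na = 0.05) {
  method <- match.arg(method)
  seq <- checkDna(seq, "primer sequence", allowN = FALSE)
  if (nchar(seq) < 8L)
    stop("primer sequence must be at least 8 bases", call. = FALSE)
  ch <- strsplit(seq, "")[[1L]]
  if (method == "wallace") {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  .nnTm(ch, 1L, length(ch), primerConc, Na)
}

## Vectorized nearest-neighbor Tm over substrings [starts, ends] of a
## character vector.  The unified parameter set is strand-symmetric
## (each step shares its value with its reverse complement, and the
## initiation term depends only on the G/C class of the terminal bases),
## so the top-strand substring gives the correct Tm for a reverse primer
## as well.
.nnTm <- function(chars, starts, ends, primerConc = 5e-7, Na = 0.05) {
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1L])
  cumH <- c(0, cumsum(.nnDH[steps]))
  cumS <- c(0, cumsum(.nnDS[steps]))
  gcClass <- chars %in% c("G", "C")
  initH <- ifelse(gcClass[starts], 0.1, 2.3) + ifelse(gcClass[ends], 0.1, 2.3)
  initS <- ifelse(gcClass[starts], -2.8, 4.1) + ifelse(gcClass[ends], -2.8, 4.1)
  dH <- cumH[ends] - cumH[starts] + initH
  dS <- cumS[ends] - cumS[starts] + initS +
    0.368 * (ends - starts) * log(Na)
  R <- 1.987
  dH * 1000 / (dS + R * log(primerConc / 4)) - 273.15
}
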