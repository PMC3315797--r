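# Core skew metric and base-counting utilities.

# ASCII code -> base index (A=1, C=2, G=3, T=4); everything else NA.
# N and other ambiguity codes are deliberately NA so they never enter
# skew denominators.
.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

#' Convert a nucleotide string to integer base codes
#'
#' @param x a single nucleotide string (upper case).
#' @return integer vector, one element per base: A=1, C=2, G=3, T=4,
#'   `NA` for N and any other ambiguity code.
#' @keywords internal
seq_codes <- function(x) {
  .BASE_CODE[utf8ToInt(x)]
}

#' Base composition counts of a sequence
#'
#' Counts A, C, G and T in a nucleotide string. N and other ambiguity
#' codes are excluded from all counts (they contribute to no base).
#'
#' @param x a single nucleotide string.
#' @return a `composition_counts` object: a named integer vector with
#'   elements `A`, `C`, `G`, `T`.
#' @examples
#' base_counts("ATGGGN")
#' @export
base_counts <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  n <- tabulate(seq_codes(toupper(x)), nbins = 4L)
  composition_counts(n[1L], n[2L], n[3L], n[4L])
}

#' Construct base composition counts
#'
#' @param nA,nC,nG,nT non-negative counts.
#' @return a named numeric vector of class `composition_counts`.
#' @export
composition_counts <- function(nA = 0, nC = 0, nG = 0, nT = 0) {
  x <- c(A = unname(nA), C = unname(nC), G = unname(nG), T = unname(nT))
  if (any(is.na(x)) || any(x < 0)) {
    stop("composition counts must be non-negative")
  }
  structure(x, class = "composition_counts")
}

#' GC or AT skew of composition counts or a sequence
#'
#' The skew statistic is (G - C)/(G + C) for the GC pair and
#' (A - T)/(A + T) for the AT pair, a symmetric measure ranging from
#' -1 (all C, resp. all T) to +1 (all G, resp. all A). When the
#' denominator is zero the skew is undefined and `NA` is returned;
#' undefined values are never coerced to 0.
#'
#' @param x a `composition_counts` object, a named vector with elements
#'   `A`,`C`,`G`,`T`, or a single nucleotide string.
#' @param pair `"GC"` or `"AT"`.
#' @return a number in \[-1, 1\], or `NA` when the pair is absent.
#' @examples
#' skew("GGGG")                      # 1
#' skew(composition_counts(nG = 3, nC = 1))  # 0.5
#' skew("AAAA")                      # NA for the GC pair
#' @export
skew <- function(x, pair = c("GC", "AT")) {
  pair <- match.arg(pair)
  if (is.character(x)) x <- base_counts(x)
  if (any(x[c("A", "C", "G", "T")] < 0)) stop("negative counts")
  if (pair == "GC") {
    num <- x[["G"]] - x[["C"]]
    den <- x[["G"]] + x[["C"]]
  } else {
    num <- x[["A"]] - x[["T"]]
    den <- x[["A"]] + x[["T"]]
  }
  if (den == 0) NA_real_ else num / den
}

# Skew from a 4-row count matrix (rows A,C,G,T), vectorised over columns.
# Returns NA where the pair denominator is zero.
skew_from_counts <- function(m, pair = c("GC", "AT")) {
  pair <- match.arg(pair)
  if (pair == "GC") {
    num <- m[3L, ] - m[2L, ]
    den <- m[3L, ] + m[2L, ]
  } else {
    num <- m[1L, ] - m[4L, ]
    den <- m[1L, ] + m[4L, ]
  }
  ifelse(den == 0, NA_real_, num / den)
}

# Reverse complement of a character vector of sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
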