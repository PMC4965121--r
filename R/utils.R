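#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

#' Convert between DNA and RNA alphabets
#'
#' Sequences live on disk as DNA (T) and inside folding/duplex logic as RNA
#' (U); these helpers convert at module boundaries.
#'
#' @param x character vector of sequences.
#' @return character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of DNA or RNA strings
#'
#' @param x character vector; alphabet is detected per element (presence of U).
#' @return character vector of reverse complements in the same alphabet.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    comp <- if (grepl("U", s)) chartr("ACGU", "UGCA", s) else chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Published summary tables print percentages with conventional half-up
#' rounding (97.495 -> 97.50), which differs from R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a total, rounded as printed in summary tables
#'
#' @param n numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 2, as in the published tables).
#' @return numeric percentage(s).
#' @export
pct <- function(n, total, digits = 2) {
  round_half_up(100 * n / total, digits)
}

random_seq <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_int <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
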