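# Thin wrappers around the ViennaRNA command-line tools. All folding and
# duplex energetics in the package go through these two entry points so the
# thermodynamic model is used consistently (single-strand MFE structures via
# RNAfold, intermolecular hybridisation via RNAduplex).

vienna_available <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAduplex"))
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s must be RNA over {A,C,G,U}; offending entry: %s",
                 what, toupper(x[bad][1])), call. = FALSE)
  }
  invisible(toupper(x))
}

#' Fold RNA sequences into minimum-free-energy secondary structures
#'
#' Computes the MFE structure of each sequence with the nearest-neighbor
#' thermodynamic model (RNAfold). Folding is deterministic: the same sequence
#' always yields the same structure and energy.
#'
#' @param sequences character vector of RNA sequences over \code{{A,C,G,U}}.
#' @return data.frame with columns \code{sequence}, \code{structure}
#'   (dot-bracket, same length as the sequence) and \code{mfe} (kcal/mol).
#' @examples
#' \dontrun{fold_rna("GGGGGGGGGGGGAAAACCCCCCCCCCCC")}
#' @export
fold_rna <- function(sequences) {
  sequences <- check_rna_alphabet(sequences)
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  if (any(nchar(sequences) < 1L)) stop("empty sequence cannot be folded")
  if (!vienna_available()) stop("RNAfold not found on the PATH")
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste0(">q", seq_along(sequences), "\n", sequences), inp)
  out <- system2("RNAfold", c("--noPS"), stdin = inp, stdout = TRUE, stderr = FALSE)
  # output: 3 lines per record (>id / sequence / structure (energy))
  sl <- out[seq(3L, length(out), by = 3L)]
  m <- regmatches(sl, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", sl))
  structure <- vapply(m, `[`, character(1), 2L)
  mfe <- as.numeric(vapply(m, `[`, character(1), 3L))
  if (anyNA(mfe) || any(nchar(structure) != nchar(sequences))) {
    stop("unexpected RNAfold output")
  }
  data.frame(sequence = sequences, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Base-pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string with balanced parentheses.
#' @return integer vector \code{p} with \code{p[i]} the partner of position
#'   \code{i}, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("(", ")", "."))) stop("invalid dot-bracket structure")
  p <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  p
}

#' Hybridisation energy of miRNA/target duplexes
#'
#' `duplex_mfe()` computes the minimum free energy of the intermolecular
#' duplex between a miRNA and candidate target sites (RNAduplex; no
#' intramolecular structure). `perfect_mfe()` is the energy of the miRNA
#' bound to its exact complement, the denominator of the MFE-ratio target
#' rule.
#'
#' @param mirna single RNA sequence, 5'->3'.
#' @param sites character vector of target site sequences, 5'->3'.
#' @return numeric vector of energies in kcal/mol (one per site).
#' @export
duplex_mfe <- function(mirna, sites) {
  mirna <- check_rna_alphabet(mirna, "miRNA")
  sites <- check_rna_alphabet(sites, "site")
  stopifnot(length(mirna) == 1L)
  if (length(sites) == 0L) return(numeric(0))
  if (!vienna_available()) stop("RNAduplex not found on the PATH")
  inp <- tempfile(fileext = ".seq")
  on.exit(unlink(inp), add = TRUE)
  writeLines(as.vector(rbind(rep(mirna, length(sites)), sites)), inp)
  out <- system2("RNAduplex", stdin = inp, stdout = TRUE, stderr = FALSE)
  out <- out[nzchar(out)]
  m <- regmatches(out, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  mfe <- as.numeric(vapply(m, `[`, character(1), 2L))
  if (length(mfe) != length(sites) || anyNA(mfe)) stop("unexpected RNAduplex output")
  mfe
}

#' @rdname duplex_mfe
#' @export
perfect_mfe <- function(mirna) {
  duplex_mfe(mirna, revcomp(check_rna_alphabet(mirna, "miRNA")))
}
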