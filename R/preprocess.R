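# Raw small-RNA read cleaning and accounting. Reads are assigned to exactly
# one category in a fixed cascade (low quality -> 3' adaptor null -> insert
# null -> 5' adaptor contaminant -> shorter than 18 nt -> poly(A) -> clean),
# so the category counts partition the high-quality total and the clean-read
# count satisfies the accounting identity of the published summary table.

FILTER_CATEGORIES <- c("adaptor3_null", "insert_null", "adaptor5_contaminant",
                       "shorter_than_18", "polyA")

#' Read-filtering summary with the published accounting identity
#'
#' Builds the per-category accounting of a small-RNA library: clean reads are
#' the high-quality reads minus the five contaminant categories, and
#' percentages are reported relative to the high-quality total (which prints
#' as 100.00).
#'
#' @param total_reads raw read count.
#' @param high_quality reads surviving the quality filter.
#' @param adaptor3_null,insert_null,adaptor5_contaminant,shorter_than_18,polyA
#'   contaminant category counts.
#' @return object of class `filter_summary` with counts, `clean_reads` and a
#'   `percentages` vector rounded half-up to 2 decimal places.
#' @examples
#' s <- filter_summary(17186803, 17103178, 6753, 3712, 31246, 386179, 115)
#' s$clean_reads        # 16675173
#' s$percentages[["clean_reads"]]  # 97.50
#' @export
filter_summary <- function(total_reads, high_quality, adaptor3_null,
                           insert_null, adaptor5_contaminant,
                           shorter_than_18, polyA) {
  counts <- as.integer(c(adaptor3_null = adaptor3_null, insert_null = insert_null,
                         adaptor5_contaminant = adaptor5_contaminant,
                         shorter_than_18 = shorter_than_18, polyA = polyA))
  names(counts) <- FILTER_CATEGORIES
  total_reads <- as.integer(total_reads)
  high_quality <- as.integer(high_quality)
  if (any(counts < 0) || high_quality < 0 || total_reads < high_quality) {
    stop("inconsistent read counts")
  }
  if (sum(counts) > high_quality) stop("category counts exceed high-quality reads")
  clean <- high_quality - sum(counts)
  structure(list(
    total_reads = total_reads, high_quality = high_quality,
    adaptor3_null = counts[["adaptor3_null"]],
    insert_null = counts[["insert_null"]],
    adaptor5_contaminant = counts[["adaptor5_contaminant"]],
    shorter_than_18 = counts[["shorter_than_18"]],
    polyA = counts[["polyA"]], clean_reads = clean,
    percentages = pct(c(high_quality = high_quality, counts, clean_reads = clean),
                      high_quality)
  ), class = "filter_summary")
}

#' @export
print.filter_summary <- function(x, ...) {
  cat("Small RNA read filtering summary\n")
  cat(sprintf("  %-22s %12s %10s\n", "category", "count", "% of HQ"))
  rows <- c("high_quality", FILTER_CATEGORIES, "clean_reads")
  for (r in rows) {
    cat(sprintf("  %-22s %12d %10.2f\n", r, as.integer(x[[r]]), x$percentages[[r]]))
  }
  cat(sprintf("  (total raw reads: %d)\n", as.integer(x$total_reads)))
  invisible(x)
}

mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

# leftmost position of a >= seed_len prefix match of `adapter` in `reads`;
# NA where absent. Vectorised over reads.
find_adapter <- function(reads, adapter, seed_len = 6L) {
  seed <- substr(adapter, 1L, seed_len)
  pos <- regexpr(seed, reads, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos), NA_integer_)
}

#' Filter and trim raw small-RNA reads
#'
#' Applies the cleaning cascade: low-quality reads (mean Phred below
#' `quality_threshold` or more than 10% N) are dropped first; the remaining
#' high-quality reads are assigned, in order, to 3' adaptor null (no match of
#' a `seed3`-nt adapter prefix), insert null (trimmed insert empty),
#' 5' adaptor contaminant (read begins with at least `seed5` nt of the 5'
#' adapter), shorter than `min_length`, poly(A) (at least `polya_frac` A
#' after trimming), or clean. The 3' adapter is trimmed from clean reads.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33, same length as sequence), e.g. from [read_fastq()].
#' @param adapter3,adapter5 adapter sequences (DNA).
#' @param quality_threshold minimum mean Phred score (default 20).
#' @param min_length minimum insert length (default 18).
#' @param seed3,seed5 minimum adapter-match lengths for the 3'/5' checks.
#' @param polya_frac fraction of A that defines a poly(A) insert.
#' @return list with `clean` (data.frame `read_id`, `sequence` of trimmed
#'   inserts), `category` (per-read category vector, aligned with `reads`)
#'   and `summary` (a [filter_summary()]).
#' @export
filter_reads <- function(reads, adapter3 = DEFAULT_ADAPTER3,
                         adapter5 = DEFAULT_ADAPTER5, quality_threshold = 20,
                         min_length = 18L, seed3 = 6L, seed5 = 8L,
                         polya_frac = 0.8) {
  stopifnot(is.data.frame(reads), nzchar(adapter3), nzchar(adapter5))
  if (nrow(reads) > 0 && any(nchar(reads$sequence) != nchar(reads$quality))) {
    bad <- which(nchar(reads$sequence) != nchar(reads$quality))[1]
    stop(sprintf("malformed FASTQ record %d: sequence/quality length mismatch", bad))
  }
  n <- nrow(reads)
  category <- rep(NA_character_, n)
  seqs <- toupper(reads$sequence)

  low_q <- mean_phred(reads$quality) < quality_threshold |
    (nchar(gsub("[^N]", "", seqs)) / pmax(1L, nchar(seqs))) > 0.10
  category[low_q] <- "low_quality"
  hq <- !low_q

  pos3 <- find_adapter(seqs, adapter3, seed3)
  category[hq & is.na(pos3)] <- "adaptor3_null"
  todo <- hq & is.na(category)

  insert <- ifelse(is.na(pos3), seqs, substr(seqs, 1L, pmax(0L, pos3 - 1L)))
  category[todo & nchar(insert) == 0L] <- "insert_null"
  todo <- hq & is.na(category)

  a5 <- substr(adapter5, nchar(adapter5) - seed5 + 1L, nchar(adapter5))
  category[todo & startsWith(insert, a5)] <- "adaptor5_contaminant"
  todo <- hq & is.na(category)

  category[todo & nchar(insert) < min_length] <- "shorter_than_18"
  todo <- hq & is.na(category)

  a_frac <- nchar(gsub("[^A]", "", insert)) / pmax(1L, nchar(insert))
  category[todo & a_frac >= polya_frac] <- "polyA"
  category[hq & is.na(category)] <- "clean"

  cnt <- function(k) sum(category == k, na.rm = TRUE)
  smry <- filter_summary(n, sum(hq), cnt("adaptor3_null"), cnt("insert_null"),
                         cnt("adaptor5_contaminant"), cnt("shorter_than_18"),
                         cnt("polyA"))
  keep <- which(category == "clean")
  list(clean = data.frame(read_id = reads$read_id[keep],
                          sequence = insert[keep], stringsAsFactors = FALSE),
       category = category, summary = smry)
}

#' Collapse clean reads to unique tags with counts
#'
#' @param sequences character vector of trimmed insert sequences (or the
#'   `clean` data.frame from [filter_reads()]).
#' @param min_length,max_length length window retained (tags outside it are
#'   dropped; the default 18-30 matches the gel-purified size fraction).
#' @return data.frame with columns `tag_id` (`t000001` style), `sequence`,
#'   `count`, sorted by decreasing count then sequence. The counts sum to the
#'   number of in-window input reads.
#' @export
collapse_tags <- function(sequences, min_length = 18L, max_length = 30L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- toupper(sequences)
  sequences <- sequences[nchar(sequences) >= min_length & nchar(sequences) <= max_length]
  if (length(sequences) == 0L) {
    return(data.frame(tag_id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out <- data.frame(tag_id = sprintf("t%06d", seq_len(nrow(out))),
                    sequence = out$sequence, count = out$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Length, first-nucleotide and positional composition of a tag set
#'
#' Computes the composition statistics reported for small-RNA libraries: the
#' length distribution, the first-nucleotide table per length (restricted to
#' `first_nt_window`, 18-25 by default), and per-position nucleotide
#' fractions. All three are reported both redundant (count-weighted) and
#' unique (per distinct tag). Nucleotides are reported in the RNA alphabet
#' (T counted as U).
#'
#' @param tags data.frame from [collapse_tags()].
#' @param first_nt_window inclusive length range of the first-nucleotide
#'   table.
#' @return list with `length_counts`, `first_nt_by_length` (matrices, one row
#'   per length) and `positional_nt_fraction` (positions x A/C/G/U, redundant
#'   weighting; rows sum to 1).
#' @export
composition_stats <- function(tags, first_nt_window = c(18L, 25L)) {
  nt <- c("A", "C", "G", "U")
  if (nrow(tags) == 0L) {
    return(list(length_counts = data.frame(length = integer(), unique = integer(),
                                           redundant = integer()),
                first_nt_by_length = list(unique = NULL, redundant = NULL),
                positional_nt_fraction = NULL))
  }
  len <- nchar(tags$sequence)
  lens <- sort(unique(len))
  length_counts <- data.frame(
    length = lens,
    unique = as.integer(tapply(rep(1L, nrow(tags)), factor(len, lens), sum)),
    redundant = as.integer(tapply(tags$count, factor(len, lens), sum)))

  first <- dna_to_rna(substr(tags$sequence, 1L, 1L))
  win <- len >= first_nt_window[1] & len <= first_nt_window[2]
  wl <- sort(unique(len[win]))
  mk <- function(w) {
    m <- matrix(0L, length(wl), 4L, dimnames = list(wl, nt))
    for (i in which(win)) {
      m[as.character(len[i]), first[i]] <- m[as.character(len[i]), first[i]] + w[i]
    }
    m
  }
  first_nt <- list(unique = mk(rep(1L, nrow(tags))), redundant = mk(tags$count))

  maxlen <- max(len)
  posm <- matrix(0, maxlen, 4L, dimnames = list(NULL, nt))
  chars <- strsplit(dna_to_rna(tags$sequence), "", fixed = TRUE)
  for (i in seq_len(nrow(tags))) {
    idx <- cbind(seq_along(chars[[i]]), match(chars[[i]], nt))
    posm[idx] <- posm[idx] + tags$count[i]
  }
  posm <- posm / pmax(1, rowSums(posm))

  list(length_counts = length_counts, first_nt_by_length = first_nt,
       positional_nt_fraction = posm)
}
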