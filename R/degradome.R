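# Degradome (PARE) analysis: per-transcript 5'-end density, cleavage-site
# validation opposite miRNA nucleotides 10-11, peak categories and t-plot
# tables. miRNA-guided cleavage leaves the 3' fragment's 5' end at the
# transcript position pairing miRNA nucleotide 10; for a site at [s, e]
# (e pairs miRNA nucleotide 1) that position is e - 9.

#' Build a degradome density file
#'
#' Maps degradome reads to the transcripts (sense strand, exact match by
#' default) and counts read 5' ends per transcript position. Multi-mapping
#' reads are counted once per transcript hit.
#'
#' @param reads data.frame with `sequence` (and optionally `read_id`).
#' @param transcripts named character vector of transcript sequences.
#' @param max_mismatches allowed substitutions (default 0: cleavage
#'   fragments are exact transcript suffixes).
#' @return named list: transcript_id -> integer vector of per-position
#'   5'-end counts (length = transcript length).
#' @export
build_density <- function(reads, transcripts, max_mismatches = 0L) {
  density <- lapply(transcripts, function(tx) integer(nchar(tx)))
  if (nrow(reads) == 0L) return(density)
  tab <- table(reads$sequence)
  useq <- names(tab); ucount <- as.integer(tab)
  for (tid in names(transcripts)) {
    subject <- Biostrings::DNAString(transcripts[[tid]])
    for (idx in split(seq_along(useq), nchar(useq))) {
      pats <- Biostrings::DNAStringSet(useq[idx])
      if (max_mismatches == 0L) {
        m <- Biostrings::matchPDict(Biostrings::PDict(pats), subject)
      } else {
        m <- lapply(seq_along(pats), function(j)
          Biostrings::matchPattern(pats[[j]], subject, max.mismatch = max_mismatches))
      }
      for (j in seq_along(idx)) {
        starts <- BiocGenerics::start(m[[j]])
        for (st in starts) {
          density[[tid]][st] <- density[[tid]][st] + ucount[idx[j]]
        }
      }
    }
  }
  density
}

#' Categorise a degradome peak
#'
#' The conventional degradome evidence classes: 0 = the position holds the
#' unique transcript maximum (and count > 1); 1 = it ties the maximum
#' (count > 1); 2 = above the median of the transcript's nonzero counts but
#' not a maximum; 3 = at or below that median but count > 1; 4 = count 1.
#' A zero count has no category (NA).
#'
#' @param density_vec integer vector of per-position counts for one
#'   transcript.
#' @param position 1-based transcript position.
#' @return integer category 0-4, or NA for a zero count.
#' @export
categorize_peak <- function(density_vec, position) {
  cnt <- density_vec[position]
  if (is.na(cnt) || cnt == 0L) return(NA_integer_)
  if (cnt == 1L) return(4L)
  mx <- max(density_vec)
  if (cnt == mx) {
    return(if (sum(density_vec == mx) == 1L) 0L else 1L)
  }
  med <- median(density_vec[density_vec > 0L])
  if (cnt > med) 2L else 3L
}

#' Detect miRNA-guided cleavage events
#'
#' For each predicted target site the expected cleavage position is the
#' transcript position paired with miRNA nucleotide 10 (`site_end - 9`,
#' i.e. between the positions pairing nucleotides 10 and 11); an event is
#' emitted iff the density there reaches `min_peak`. Events are reported per
#' miRNA without suppression, so positions shared by miRNAs with identical
#' sequences yield one event each.
#'
#' @param targets data.frame from [scan_transcriptome()].
#' @param density density list from [build_density()] on the same
#'   transcripts.
#' @param min_peak minimum 5'-end count at the cleavage position.
#' @return data.frame with `mirna_id`, `transcript_id`, `cleavage_position`,
#'   `peak_count`, `category`, `site_start`, `site_end`.
#' @export
detect_cleavage <- function(targets, density, min_peak = 1L) {
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    tid <- targets$transcript_id[i]
    if (is.null(density[[tid]])) stop("no density for transcript ", tid)
    cp <- targets$site_end[i] - 9L
    if (cp < 1L || cp > length(density[[tid]])) {
      stop("cleavage position outside transcript ", tid)
    }
    cnt <- density[[tid]][cp]
    if (cnt >= min_peak && cnt > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = targets$mirna_id[i], transcript_id = tid,
        cleavage_position = cp, peak_count = cnt,
        category = categorize_peak(density[[tid]], cp),
        site_start = targets$site_start[i], site_end = targets$site_end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      cleavage_position = integer(), peak_count = integer(),
                      category = integer(), site_start = integer(),
                      site_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$transcript_id, out$cleavage_position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position t-plot table for one transcript
#'
#' @param transcript_id transcript to tabulate.
#' @param density density list from [build_density()].
#' @param events cleavage events from [detect_cleavage()].
#' @return data.frame with `position`, `count`, `is_cleavage_site`, ready
#'   for plotting.
#' @export
tplot_data <- function(transcript_id, density, events) {
  if (is.null(density[[transcript_id]])) {
    stop("unknown transcript: ", transcript_id)
  }
  d <- density[[transcript_id]]
  if (length(d) == 0L) {
    return(data.frame(position = integer(), count = integer(),
                      is_cleavage_site = logical()))
  }
  cps <- events$cleavage_position[events$transcript_id == transcript_id]
  data.frame(position = seq_along(d), count = d,
             is_cleavage_site = seq_along(d) %in% cps)
}

#' Plot a degradome t-plot
#'
#' @param transcript_id transcript to plot.
#' @param density density list from [build_density()].
#' @param events cleavage events from [detect_cleavage()].
#' @param ... passed to [plot()].
#' @return the t-plot table, invisibly.
#' @export
plot_tplot <- function(transcript_id, density, events, ...) {
  td <- tplot_data(transcript_id, density, events)
  plot(td$position, td$count, type = "h", xlab = "transcript position",
       ylab = "degradome 5'-end count", main = transcript_id, ...)
  marked <- td[td$is_cleavage_site, , drop = FALSE]
  if (nrow(marked) > 0L) {
    graphics::points(marked$position, marked$count, col = "red", pch = 19)
  }
  invisible(td)
}
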