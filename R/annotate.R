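# Genome mapping and annotation cascade. Tags are mapped exactly (both
# strands, all occurrences), then classified into ncRNA / exon / intron /
# repeat / miRNA / unannotated categories by a configurable precedence
# order, reproducing the published per-category unique/redundant accounting.

#' Map tags to genome scaffolds
#'
#' Reports every occurrence of every tag on both strands. The default is
#' perfect matching (0 mismatches), matching the genome-mapping step of the
#' published workflow.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param genome named character vector of scaffold sequences (DNA).
#' @param max_mismatches allowed substitutions (0 uses a fast dictionary
#'   match; small positive values fall back to per-tag scanning).
#' @return data.frame with columns `tag_id`, `tag_sequence`, `scaffold`,
#'   `start`, `end` (1-based inclusive), `strand`, `mismatches`. Tags absent
#'   from the result are unmapped.
#' @export
map_tags <- function(tags, genome, max_mismatches = 0L) {
  if (length(genome) == 0L) stop("empty genome")
  if (nrow(tags) == 0L) {
    return(data.frame(tag_id = character(), tag_sequence = character(),
                      scaffold = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  hit_rows <- list()
  add_hits <- function(idx, scaf, starts, strand, mm, width) {
    if (length(starts) == 0L) return()
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      tag_id = tags$tag_id[idx], tag_sequence = tags$sequence[idx],
      scaffold = scaf, start = starts, end = starts + width - 1L,
      strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  fwd <- Biostrings::DNAStringSet(tags$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  for (scaf in names(genome)) {
    subject <- Biostrings::DNAString(genome[[scaf]])
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") fwd else rev
      if (max_mismatches == 0L) {
        # PDict needs constant width: match one dictionary per tag length
        for (idx in split(seq_len(nrow(tags)), nchar(tags$sequence))) {
          m <- Biostrings::matchPDict(Biostrings::PDict(pats[idx]), subject)
          for (j in seq_along(idx)) {
            add_hits(idx[j], scaf, BiocGenerics::start(m[[j]]), strand, 0L,
                     nchar(tags$sequence[idx[j]]))
          }
        }
      } else {
        for (i in seq_len(nrow(tags))) {
          m <- Biostrings::matchPattern(pats[[i]], subject,
                                        max.mismatch = max_mismatches)
          if (length(m) == 0L) next
          mm <- Biostrings::neditStartingAt(pats[[i]], subject,
                                            starting.at = BiocGenerics::start(m))
          add_hits(i, scaf, BiocGenerics::start(m), strand, as.integer(mm),
                   nchar(tags$sequence[i]))
        }
      }
    }
  }
  if (length(hit_rows) == 0L) {
    return(map_tags(tags[0, , drop = FALSE], genome))
  }
  out <- do.call(rbind, hit_rows)
  out <- out[order(out$tag_id, out$scaffold, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

DEFAULT_PRECEDENCE <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                        "exon", "intron", "unannotated")

hamming_le <- function(a, b, limit) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(charToRaw(a) != charToRaw(b)) <= limit
}

#' Classify tags into annotation categories
#'
#' Each tag receives exactly one category. Tags matching a known mature
#' miRNA sequence (perfect match or up to `mirna_mismatches` substitutions,
#' same length) are `miRNA`; otherwise the genomic hits are overlapped
#' (at least 1 nt) with the annotation features and the first category in
#' `precedence` wins. Exon and intron assignments are split into sense /
#' antisense by comparing the hit strand with the feature strand (sense
#' preferred when both occur). Mapped tags matching nothing are
#' `unannotated`; unmapped tags are `unmapped`.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param hits data.frame from [map_tags()].
#' @param annotation GRanges with a `type` metadata column using the
#'   category names above.
#' @param known_mirnas character vector of known mature miRNA sequences
#'   (DNA or RNA), or NULL.
#' @param precedence category order; must cover all feature types present.
#' @param mirna_mismatches mismatch tolerance for the known-miRNA match.
#' @return list with `category` (data.frame `tag_id`, `category`) and
#'   `summary` (a [category_summary()] data.frame over the clean-tag
#'   partition, unmapped counted as unannotated as in the published table).
#' @export
classify_tags <- function(tags, hits, annotation, known_mirnas = NULL,
                          precedence = DEFAULT_PRECEDENCE,
                          mirna_mismatches = 1L) {
  feature_types <- unique(as.character(annotation$type))
  unknown <- setdiff(feature_types, precedence)
  if (length(unknown) > 0L) {
    stop("annotation types missing from precedence list: ",
         paste(unknown, collapse = ", "))
  }
  category <- rep(NA_character_, nrow(tags))

  if (!is.null(known_mirnas) && length(known_mirnas) > 0L) {
    db <- unique(rna_to_dna(known_mirnas))
    is_mir <- vapply(tags$sequence, function(s) {
      any(vapply(db, hamming_le, logical(1), a = s, limit = mirna_mismatches))
    }, logical(1), USE.NAMES = FALSE)
    category[is_mir] <- "miRNA"
  }

  mapped <- tags$tag_id %in% hits$tag_id
  todo <- which(is.na(category) & mapped)
  if (length(todo) > 0L && length(annotation) > 0L) {
    h <- hits[hits$tag_id %in% tags$tag_id[todo], , drop = FALSE]
    gr <- GenomicRanges::GRanges(h$scaffold,
                                 IRanges::IRanges(h$start, h$end),
                                 strand = h$strand)
    ov <- GenomicRanges::findOverlaps(gr, annotation, minoverlap = 1L,
                                      ignore.strand = TRUE)
    if (length(ov) > 0L) {
      ftype <- as.character(annotation$type[S4Vectors::subjectHits(ov)])
      fstrand <- as.character(BiocGenerics::strand(annotation))[S4Vectors::subjectHits(ov)]
      hstrand <- h$strand[S4Vectors::queryHits(ov)]
      sense <- fstrand == "*" | fstrand == hstrand
      per_tag <- split(paste(ftype, ifelse(sense, "sense", "antisense"), sep = ":"),
                       h$tag_id[S4Vectors::queryHits(ov)])
      base_rank <- setNames(seq_along(precedence), precedence)
      tag_index <- setNames(seq_len(nrow(tags)), tags$tag_id)
      for (tid in names(per_tag)) {
        idx <- tag_index[[tid]]
        if (!is.na(category[idx])) next
        parts <- unique(per_tag[[tid]])
        base <- sub(":.*$", "", parts)
        best <- base[which.min(base_rank[base])]
        if (best %in% c("exon", "intron")) {
          sense_hit <- paste0(best, ":sense") %in% parts
          category[idx] <- paste0(best, "_", if (sense_hit) "sense" else "antisense")
        } else {
          category[idx] <- best
        }
      }
    }
  }
  category[is.na(category) & mapped] <- "unannotated"
  category[is.na(category)] <- "unmapped"

  lev <- c("exon_antisense", "exon_sense", "intron_antisense", "intron_sense",
           "miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "repeat", "unannotated")
  summary_cat <- ifelse(category == "unmapped", "unannotated", category)
  f <- factor(summary_cat, levels = lev)
  uniq <- as.integer(table(f))
  redun <- as.integer(tapply(tags$count, f, sum, default = 0L))
  keep <- uniq > 0L | lev %in% c("unannotated")
  smry <- category_summary(setNames(uniq, lev)[keep], setNames(redun, lev)[keep])

  list(category = data.frame(tag_id = tags$tag_id, category = category,
                             stringsAsFactors = FALSE),
       summary = smry)
}

#' Per-category unique/redundant summary with printed percentages
#'
#' Builds the published-style annotation summary: one row per category with
#' unique and redundant counts and percentages of the respective totals,
#' rounded half-up to 2 decimal places.
#'
#' @param unique_counts named integer vector of unique tag counts.
#' @param redundant_counts named integer vector of redundant read counts
#'   (same names).
#' @return data.frame with columns `category`, `unique_count`, `unique_pct`,
#'   `redundant_count`, `redundant_pct` plus a `Total` row.
#' @export
category_summary <- function(unique_counts, redundant_counts) {
  stopifnot(identical(names(unique_counts), names(redundant_counts)))
  tu <- sum(unique_counts); tr <- sum(redundant_counts)
  data.frame(
    category = c(names(unique_counts), "Total"),
    unique_count = c(unname(unique_counts), tu),
    unique_pct = c(pct(unname(unique_counts), tu), 100.00),
    redundant_count = c(unname(redundant_counts), tr),
    redundant_pct = c(pct(unname(redundant_counts), tr), 100.00),
    stringsAsFactors = FALSE)
}
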