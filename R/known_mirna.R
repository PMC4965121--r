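# Known-miRNA assignment against miRBase-style mature/precursor databases,
# family grouping, and the cross-species conservation matrix.

#' Parse the family from a miRBase-style miRNA id
#'
#' `ppe-miR156a` -> `miR156`; the family is "miR" plus the leading integer
#' run of the numeric suffix.
#'
#' @param ids character vector of miRNA ids.
#' @return character vector of family names (NA where no miR number parses).
#' @export
mirna_family <- function(ids) {
  m <- regmatches(ids, regexec("[mM][iI][rR]-?([0-9]+)", ids))
  vapply(m, function(x) if (length(x) == 2L) paste0("miR", x[2]) else NA_character_,
         character(1))
}

mirna_species <- function(ids) {
  ifelse(grepl("^[a-z]{3,4}-", ids), sub("-.*$", "", ids), NA_character_)
}

#' Identify known miRNAs among collapsed tags
#'
#' Each tag is aligned against the mature database (same-length comparison,
#' substitutions only) and reported with its best (fewest-mismatch) hit
#' within `max_mismatches`; ties break by lexicographic miRNA id. Tags with
#' no mature hit are optionally matched inside precursor (hairpin) sequences
#' with the same tolerance.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param mature_db named character vector of mature miRNA sequences
#'   (names = miRBase-style ids, e.g. `ppe-miR156a`); RNA or DNA alphabet.
#' @param hairpin_db optional named character vector of precursor sequences.
#' @param max_mismatches substitution tolerance (default 2).
#' @return data.frame with columns `tag_id`, `tag_sequence`, `count`,
#'   `mirna_id`, `family`, `source_species`, `mismatches`, one row per tag
#'   with a hit.
#' @export
identify_known <- function(tags, mature_db, hairpin_db = NULL, max_mismatches = 2L) {
  if (length(mature_db) == 0L) stop("empty mature miRNA database")
  db <- setNames(rna_to_dna(mature_db), names(mature_db))
  db <- db[order(names(db))]
  db_len <- nchar(db)
  db_raw <- lapply(db, charToRaw)
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    sr <- charToRaw(s)
    cand <- which(db_len == length(sr))
    best_id <- NA_character_; best_mm <- NA_integer_
    if (length(cand) > 0L) {
      mm <- vapply(db_raw[cand], function(r) sum(r != sr), integer(1))
      j <- which(mm <= max_mismatches)
      if (length(j) > 0L) {
        jbest <- j[order(mm[j], names(db)[cand][j])][1]
        best_id <- names(db)[cand][jbest]
        best_mm <- mm[jbest]
      }
    }
    if (is.na(best_id) && !is.null(hairpin_db) && length(hairpin_db) > 0L) {
      hp <- setNames(rna_to_dna(hairpin_db), names(hairpin_db))
      for (hid in sort(names(hp))) {
        m <- Biostrings::matchPattern(s, Biostrings::DNAString(hp[[hid]]),
                                      max.mismatch = max_mismatches)
        if (length(m) > 0L) {
          best_id <- hid
          best_mm <- min(Biostrings::neditStartingAt(
            Biostrings::DNAString(s), Biostrings::DNAString(hp[[hid]]),
            starting.at = BiocGenerics::start(m)))
          break
        }
      }
    }
    if (!is.na(best_id)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tags$tag_id[i], tag_sequence = s, count = tags$count[i],
        mirna_id = best_id, family = mirna_family(best_id),
        source_species = mirna_species(best_id), mismatches = best_mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tag_id = character(), tag_sequence = character(),
                      count = integer(), mirna_id = character(),
                      family = character(), source_species = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate known-miRNA hits by family
#'
#' @param hits data.frame from [identify_known()].
#' @return data.frame with per-family total read counts and member tag
#'   numbers, sorted by decreasing count.
#' @export
family_counts <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(family = character(), n_tags = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(cbind(count = hits$count), by = list(family = hits$family), sum)
  agg$n_tags <- as.integer(table(hits$family)[agg$family])
  agg <- agg[order(-agg$count, agg$family), c("family", "n_tags", "count")]
  rownames(agg) <- NULL
  agg
}

#' Cross-species conservation matrix of miRNA families
#'
#' For every family observed in the hits and every species database, the
#' cell is `identical` when some member tag exactly matches a mature miRNA
#' of that family in that species, `variant` when the best match has at most
#' `max_mismatches` substitutions, and `absent` otherwise. The conventional
#' text encoding is `++` / `+` / blank.
#'
#' @param hits data.frame from [identify_known()].
#' @param species_dbs named list: species -> named character vector of
#'   mature sequences with miRBase-style ids.
#' @param max_mismatches tolerance for the `variant` call.
#' @return character matrix family x species over
#'   {"identical","variant","absent"}, with a `symbols` attribute holding
#'   the `++`/`+`/blank rendering.
#' @export
conservation_matrix <- function(hits, species_dbs, max_mismatches = 2L) {
  fams <- sort(unique(hits$family[!is.na(hits$family)]))
  out <- matrix("absent", length(fams), length(species_dbs),
                dimnames = list(fams, names(species_dbs)))
  for (sp in names(species_dbs)) {
    db <- rna_to_dna(species_dbs[[sp]])
    db_fam <- mirna_family(names(db))
    for (fam in fams) {
      seqs <- unique(hits$tag_sequence[hits$family == fam])
      cand <- db[!is.na(db_fam) & db_fam == fam]
      if (length(cand) == 0L) next
      mm <- outer(seqs, cand, Vectorize(function(a, b) {
        if (nchar(a) != nchar(b)) Inf else sum(charToRaw(a) != charToRaw(b))
      }))
      best <- min(mm)
      out[fam, sp] <- if (best == 0) "identical"
                      else if (best <= max_mismatches) "variant" else "absent"
    }
  }
  sym <- out
  sym[] <- c(identical = "++", variant = "+", absent = "")[out]
  attr(out, "symbols") <- sym
  out
}
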