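# Plant miRNA target prediction with the six classical complementarity rules
# (Allen/Schwab-style): positional mismatch scoring with G:U wobble counted
# as half a mismatch, plus an MFE-ratio filter against the perfect duplex.
# Duplexes are ungapped: a site has exactly the miRNA's length and miRNA
# position i (1 = 5' end) pairs the site position site_end - i + 1
# (antiparallel).

#' Target-prediction rule set
#'
#' The six plant miRNA target criteria: (1) total mismatch score (G:U = 0.5)
#' at most `max_total`; (2) at most `max_adjacent_mm` adjacent mismatches;
#' (3) no adjacent mismatches within miRNA positions
#' `no_adjacent_mm_range`; (4) no mismatch at positions `no_mm_positions`;
#' (5) mismatch score over positions 1-12 at most `max_score_1_12`;
#' (6) duplex MFE at least `min_mfe_ratio` of the perfect-complement MFE.
#'
#' @param max_total maximum total mismatch score (default 4).
#' @param max_adjacent_mm maximum run length of adjacent mismatches.
#' @param no_adjacent_mm_range positions (inclusive) where adjacent
#'   mismatches are forbidden outright.
#' @param no_mm_positions positions where any mismatch is forbidden.
#' @param max_score_1_12 maximum mismatch score over positions 1-12.
#' @param min_mfe_ratio minimum duplex-to-perfect MFE ratio.
#' @param gu_breaks_adjacency if TRUE (default) a G:U wobble interrupts a run
#'   of mismatches for rules 2-3; the strict mode (FALSE) lets wobbles extend
#'   adjacency.
#' @return object of class `target_rules`.
#' @export
target_rules <- function(max_total = 4.0, max_adjacent_mm = 2L,
                         no_adjacent_mm_range = c(2L, 12L),
                         no_mm_positions = c(10L, 11L),
                         max_score_1_12 = 2.5, min_mfe_ratio = 0.75,
                         gu_breaks_adjacency = TRUE) {
  structure(list(max_total = max_total, max_adjacent_mm = as.integer(max_adjacent_mm),
                 no_adjacent_mm_range = as.integer(no_adjacent_mm_range),
                 no_mm_positions = as.integer(no_mm_positions),
                 max_score_1_12 = max_score_1_12, min_mfe_ratio = min_mfe_ratio,
                 gu_breaks_adjacency = isTRUE(gu_breaks_adjacency)),
            class = "target_rules")
}

# pair state codes: integers 0 = WC, 1 = GU, 2 = MM
STATE_LEVELS <- c("WC", "GU", "MM")

pair_state_matrix <- local({
  m <- matrix(2L, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  m["A", "U"] <- m["U", "A"] <- 0L
  m["G", "C"] <- m["C", "G"] <- 0L
  m["G", "U"] <- m["U", "G"] <- 1L
  m
})

seq_to_int <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
}

#' Align a miRNA against a candidate target window
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param window target site sequence 5'->3', same length as the miRNA.
#' @return character vector of per-position states (`"WC"`, `"GU"`, `"MM"`),
#'   indexed by miRNA position (1 = miRNA 5' end, which pairs the 3' end of
#'   the site).
#' @export
align_site <- function(mirna, window) {
  mirna <- dna_to_rna(mirna); window <- dna_to_rna(window)
  if (nchar(mirna) != nchar(window)) {
    stop("site window must have the same length as the miRNA")
  }
  m <- seq_to_int(mirna)
  w <- rev(seq_to_int(window))
  if (anyNA(m) || anyNA(w)) stop("sequences must be over {A,C,G,U}/{A,C,G,T}")
  STATE_LEVELS[pair_state_matrix[cbind(m, w)] + 1L]
}

#' Mismatch score of an alignment
#'
#' Counts mismatches plus half a mismatch per G:U wobble, optionally over a
#' positional range.
#'
#' @param states state vector from [align_site()].
#' @param positions optional integer positions to restrict the score to.
#' @return half-integer score.
#' @export
mismatch_score <- function(states, positions = NULL) {
  if (!is.null(positions)) states <- states[positions[positions <= length(states)]]
  sum(states == "MM") + 0.5 * sum(states == "GU")
}

longest_mm_run <- function(states, count_gu = FALSE) {
  is_mm <- states == "MM" | (count_gu & states == "GU")
  if (!any(is_mm)) return(0L)
  r <- rle(is_mm)
  max(r$lengths[r$values])
}

#' Apply the six target rules to an alignment
#'
#' @param alignment either a state vector from [align_site()] or a list with
#'   elements `states` and `mfe_ratio`.
#' @param rules a [target_rules()] object.
#' @param mfe_ratio duplex-to-perfect MFE ratio; may instead be supplied in
#'   `alignment`. If `NA`, rule 6 is reported `NA` and excluded from the
#'   overall verdict.
#' @return list with logical elements `rule1`..`rule6` and `overall`.
#' @export
apply_target_rules <- function(alignment, rules = target_rules(), mfe_ratio = NA_real_) {
  if (is.list(alignment)) {
    mfe_ratio <- alignment$mfe_ratio %||% mfe_ratio
    states <- alignment$states
  } else {
    states <- alignment
  }
  L <- length(states)
  count_gu <- !rules$gu_breaks_adjacency
  rng <- rules$no_adjacent_mm_range
  rng_pos <- seq(max(1L, rng[1]), min(L, rng[2]))
  in_rng <- states[rng_pos] == "MM" | (count_gu & states[rng_pos] == "GU")
  rep <- list(
    rule1 = mismatch_score(states) <= rules$max_total,
    rule2 = longest_mm_run(states, count_gu) <= rules$max_adjacent_mm,
    rule3 = !any(in_rng[-1] & in_rng[-length(in_rng)]),
    rule4 = !any(states[rules$no_mm_positions[rules$no_mm_positions <= L]] == "MM"),
    rule5 = mismatch_score(states, 1:12) <= rules$max_score_1_12,
    rule6 = if (is.na(mfe_ratio)) NA else mfe_ratio >= rules$min_mfe_ratio
  )
  rep$overall <- all(unlist(rep[1:5])) && (is.na(rep$rule6) || rep$rule6)
  rep
}

# vectorised rules 1-5 over all windows of one transcript for one miRNA;
# returns candidate site starts (rule 6 is applied later, only to survivors)
scan_positional <- function(m_int, t_int, rules) {
  L <- length(m_int)
  n <- length(t_int)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  st <- matrix(0L, nrow = L, ncol = nw)
  for (i in seq_len(L)) {
    # miRNA position i pairs transcript position s + L - i for window start s
    st[i, ] <- pair_state_matrix[cbind(m_int[i], t_int[(L - i + 1L):(n - i + 1L)])]
  }
  mm <- st == 2L
  adj_mm <- if (rules$gu_breaks_adjacency) mm else st >= 1L
  gu <- st == 1L
  score <- colSums(mm) + 0.5 * colSums(gu)
  ok <- score <= rules$max_total
  # rule 5
  p12 <- seq_len(min(12L, L))
  ok <- ok & (colSums(mm[p12, , drop = FALSE]) + 0.5 * colSums(gu[p12, , drop = FALSE])) <= rules$max_score_1_12
  # rule 4
  for (p in rules$no_mm_positions[rules$no_mm_positions <= L]) ok <- ok & !mm[p, ]
  # rule 2: longest mismatch run
  run <- integer(nw); mx <- integer(nw)
  for (i in seq_len(L)) {
    run <- ifelse(adj_mm[i, ], run + 1L, 0L)
    mx <- pmax(mx, run)
  }
  ok <- ok & mx <= rules$max_adjacent_mm
  # rule 3: adjacency within the protected 5' range
  rng <- rules$no_adjacent_mm_range
  for (i in seq(max(1L, rng[1]), min(L, rng[2]) - 1L)) {
    ok <- ok & !(adj_mm[i, ] & adj_mm[i + 1L, ])
  }
  which(ok)
}

#' Scan a transcriptome for miRNA target sites
#'
#' Tests every ungapped window of every transcript against every miRNA with
#' the six target rules. Rules 1-5 are positional; rule 6 (MFE ratio) is
#' evaluated with the duplex energy model on the survivors only. Many-to-many
#' hits are kept: one transcript may be targeted by many miRNAs and one miRNA
#' may target many transcripts.
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param rules a [target_rules()] object.
#' @return data.frame of passing target alignments, sorted by
#'   (mirna_id, transcript_id, site_start), with per-position states encoded
#'   as a comma-separated string, the mismatch score, duplex/perfect MFE and
#'   their ratio.
#' @export
scan_transcriptome <- function(mirnas, transcripts, rules = target_rules()) {
  if (is.null(names(mirnas)) || is.null(names(transcripts))) {
    stop("mirnas and transcripts must be named")
  }
  mirnas <- setNames(dna_to_rna(mirnas), names(mirnas))
  transcripts <- setNames(dna_to_rna(transcripts), names(transcripts))
  t_ints <- lapply(transcripts, seq_to_int)
  rows <- list()
  for (mid in names(mirnas)) {
    mseq <- mirnas[[mid]]
    m_int <- seq_to_int(mseq)
    L <- length(m_int)
    pm <- NULL
    for (tid in names(transcripts)) {
      starts <- scan_positional(m_int, t_ints[[tid]], rules)
      if (length(starts) == 0L) next
      sites <- substring(transcripts[[tid]], starts, starts + L - 1L)
      dmfe <- duplex_mfe(mseq, sites)
      if (is.null(pm)) pm <- perfect_mfe(mseq)
      ratio <- ifelse(dmfe < 0 & pm < 0, dmfe / pm, 0)
      keep <- ratio >= rules$min_mfe_ratio
      if (!any(keep)) next
      states_str <- vapply(sites[keep], function(s) {
        paste(align_site(mseq, s), collapse = ",")
      }, character(1), USE.NAMES = FALSE)
      score <- vapply(sites[keep], function(s) mismatch_score(align_site(mseq, s)),
                      numeric(1), USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, mirna_sequence = mseq, transcript_id = tid,
        site_start = starts[keep], site_end = starts[keep] + L - 1L,
        site_sequence = sites[keep], states = states_str,
        mismatch_score = score, duplex_mfe = dmfe[keep], perfect_mfe = pm,
        mfe_ratio = ratio[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(), mirna_sequence = character(),
                      transcript_id = character(), site_start = integer(),
                      site_end = integer(), site_sequence = character(),
                      states = character(), mismatch_score = numeric(),
                      duplex_mfe = numeric(), perfect_mfe = numeric(),
                      mfe_ratio = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- unique(res)
  res <- res[order(res$mirna_id, res$transcript_id, res$site_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Render a miRNA/target alignment as text
#'
#' Produces the conventional three-line rendering with the miRNA on top
#' (3'->5') over the target site (5'->3'), `|` for Watson-Crick pairs and
#' `o` for G:U wobbles.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site target site sequence 5'->3'.
#' @return character vector of three lines.
#' @export
format_target_alignment <- function(mirna, site) {
  states <- align_site(mirna, site)
  mid <- rev(c("|", "o", " ")[match(states, STATE_LEVELS)])
  c(paste0("miRNA  3' ", paste(rev(strsplit(dna_to_rna(mirna), "")[[1]]), collapse = ""), " 5'"),
    paste0("          ", paste(mid, collapse = "")),
    paste0("target 5' ", dna_to_rna(site), " 3'"))
}
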