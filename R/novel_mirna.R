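# Novel miRNA prediction from unannotated genome-mapped tags: loci are
# clustered, candidate precursor windows are excised around the dominant
# tag, folded (RNAfold), reduced to miRNA/miRNA* duplex metrics, and judged
# by the nine structural criteria (MIREAP-style). The star arm is inferred
# from the fold with the canonical 2-nt 3' overhang of Dicer processing.

#' Nine-criterion rule set for novel miRNA prediction
#'
#' The criteria a candidate hairpin must meet: mature length within
#' `mature_len`, reference (dominant tag) length within `ref_len`, at most
#' `max_ref_copies` genomic loci for the mature tag, precursor MFE at most
#' `mfe_max` kcal/mol, at most `max_loop_space` nt between miRNA and miRNA*,
#' at least `min_paired` miRNA/miRNA* base pairs, largest duplex bulge at
#' most `max_bulge` nt, duplex asymmetry at most `max_asymmetry` nt, and at
#' least `flank_length` nt of precursor flanking the duplex on both sides.
#' `min_read_count` is the read-support floor applied by [predict_novel()];
#' `cluster_gap` and `max_window_ext` control locus clustering and the
#' excision window search.
#'
#' @param mature_len,ref_len inclusive length windows (nt).
#' @param max_ref_copies maximum genomic copy number of the mature tag.
#' @param mfe_max maximum precursor MFE (kcal/mol).
#' @param max_loop_space maximum miRNA/miRNA* spacing (nt).
#' @param min_paired minimum miRNA/miRNA* base pairs.
#' @param max_bulge maximum duplex bulge (nt).
#' @param max_asymmetry maximum duplex asymmetry (nt).
#' @param flank_length precursor flank beyond the duplex (nt).
#' @param min_read_count minimum mature read count.
#' @param cluster_gap maximum gap when clustering hits into loci (nt).
#' @param max_window_ext largest excision extension tried beyond the mature
#'   tag (nt); slightly beyond `max_loop_space` so over-long spacings are
#'   observed and rejected rather than never excised.
#' @return object of class `novel_criteria`.
#' @export
novel_criteria <- function(mature_len = c(18L, 25L), ref_len = c(20L, 23L),
                           max_ref_copies = 20L, mfe_max = -18.0,
                           max_loop_space = 300L, min_paired = 16L,
                           max_bulge = 4L, max_asymmetry = 4L,
                           flank_length = 20L, min_read_count = 5L,
                           cluster_gap = 200L, max_window_ext = 360L) {
  stopifnot(mature_len[1] <= mature_len[2], ref_len[1] <= ref_len[2])
  structure(list(mature_len = as.integer(mature_len), ref_len = as.integer(ref_len),
                 max_ref_copies = as.integer(max_ref_copies), mfe_max = mfe_max,
                 max_loop_space = as.integer(max_loop_space),
                 min_paired = as.integer(min_paired), max_bulge = as.integer(max_bulge),
                 max_asymmetry = as.integer(max_asymmetry),
                 flank_length = as.integer(flank_length),
                 min_read_count = as.integer(min_read_count),
                 cluster_gap = as.integer(cluster_gap),
                 max_window_ext = as.integer(max_window_ext)),
            class = "novel_criteria")
}

NOVEL_CRITERION_NAMES <- c("mature_len", "ref_len", "max_ref_copies", "mfe",
                           "loop_space", "min_paired", "max_bulge",
                           "max_asymmetry", "flank")

#' miRNA/miRNA* duplex metrics of a folded hairpin candidate
#'
#' Reduces a candidate's MFE structure to the duplex quantities the criteria
#' judge. The star arm is the set of positions pairing the mature region;
#' `paired_bases` counts mature positions paired outside the mature region,
#' `max_bulge` is the longest unpaired run interior to the duplex on either
#' strand, `asymmetry` the absolute difference of interior unpaired counts
#' between the two strands, and `loop_space` the number of nt between the
#' mature region and its partner region. Reported star coordinates apply the
#' 2-nt 3' overhang rule to the partner span.
#'
#' @param structure dot-bracket structure of the precursor.
#' @param mature_start,mature_end 1-based mature coordinates within the
#'   precursor.
#' @return list with `paired_bases`, `max_bulge`, `asymmetry`, `loop_space`,
#'   `star_start`, `star_end`, `flank5`, `flank3`, or NULL when the mature
#'   region pairs nothing outside itself (duplex undefined).
#' @export
duplex_metrics <- function(structure, mature_start, mature_end) {
  pt <- pair_table(structure)
  n <- length(pt)
  ms <- as.integer(mature_start); me <- as.integer(mature_end)
  stopifnot(ms >= 1L, me <= n, ms < me)
  partners <- pt[ms:me]
  paired <- partners != 0L & (partners < ms | partners > me)
  if (!any(paired)) return(NULL)
  p_idx <- which(paired)
  span_m <- seq(min(p_idx), max(p_idx)) + ms - 1L       # mature duplex span
  pmin <- min(partners[paired]); pmax <- max(partners[paired])
  span_s <- seq(pmin, pmax)                              # star duplex span
  unp_m <- !(pt[span_m] %in% span_s) | pt[span_m] == 0L
  unp_s <- !(pt[span_s] %in% span_m) | pt[span_s] == 0L
  run_max <- function(x) if (!any(x)) 0L else max(rle(x)$lengths[rle(x)$values])
  star_after <- pmin > me
  shift <- if (star_after) 2L else -2L
  star_start <- max(1L, pmin + shift)
  star_end <- min(n, pmax + shift)
  # flanks measured beyond the duplex span itself (not the shifted star)
  lo <- min(ms, pmin); hi <- max(me, pmax)
  list(paired_bases = sum(paired),
       max_bulge = max(run_max(unp_m), run_max(unp_s)),
       asymmetry = abs(sum(unp_m) - sum(unp_s)),
       loop_space = if (star_after) pmin - me - 1L else ms - pmax - 1L,
       star_start = star_start, star_end = star_end,
       flank5 = lo - 1L, flank3 = n - hi)
}

#' Evaluate the nine novel-miRNA criteria on a candidate
#'
#' All nine checks are evaluated independently and reported with their
#' measured values; the candidate passes overall iff every check passes.
#'
#' @param candidate list with at least `precursor`, `structure`, `mfe`,
#'   `mature_start`, `mature_end` (a hairpin candidate from
#'   [excise_candidates()]).
#' @param metrics duplex metrics from [duplex_metrics()] (NULL rejects).
#' @param read_count mature tag read count (used by [predict_novel()]'s
#'   support filter, echoed in the report).
#' @param criteria a [novel_criteria()] object.
#' @param n_genome_copies genomic copy number of the mature tag.
#' @return list with `report` (data.frame criterion/value/pass over the nine
#'   criteria) and `overall`.
#' @export
apply_novel_criteria <- function(candidate, metrics, read_count = NA_integer_,
                                 criteria = novel_criteria(),
                                 n_genome_copies = 1L) {
  mlen <- candidate$mature_end - candidate$mature_start + 1L
  if (is.null(metrics)) {
    metrics <- list(paired_bases = 0L, max_bulge = NA_integer_,
                    asymmetry = NA_integer_, loop_space = NA_integer_,
                    flank5 = NA_integer_, flank3 = NA_integer_)
  }
  vals <- c(mature_len = mlen, ref_len = mlen, max_ref_copies = n_genome_copies,
            mfe = candidate$mfe, loop_space = metrics$loop_space,
            min_paired = metrics$paired_bases, max_bulge = metrics$max_bulge,
            max_asymmetry = metrics$asymmetry,
            flank = min(metrics$flank5, metrics$flank3))
  pass <- c(
    mature_len = mlen >= criteria$mature_len[1] && mlen <= criteria$mature_len[2],
    ref_len = mlen >= criteria$ref_len[1] && mlen <= criteria$ref_len[2],
    max_ref_copies = n_genome_copies <= criteria$max_ref_copies,
    mfe = candidate$mfe <= criteria$mfe_max,
    loop_space = !is.na(metrics$loop_space) && metrics$loop_space <= criteria$max_loop_space,
    min_paired = metrics$paired_bases >= criteria$min_paired,
    max_bulge = !is.na(metrics$max_bulge) && metrics$max_bulge <= criteria$max_bulge,
    max_asymmetry = !is.na(metrics$asymmetry) && metrics$asymmetry <= criteria$max_asymmetry,
    flank = !is.na(vals[["flank"]]) && vals[["flank"]] >= criteria$flank_length)
  list(report = data.frame(criterion = NOVEL_CRITERION_NAMES,
                           value = unname(vals[NOVEL_CRITERION_NAMES]),
                           pass = unname(pass[NOVEL_CRITERION_NAMES]),
                           stringsAsFactors = FALSE),
       overall = all(pass), read_count = read_count)
}

cluster_hits <- function(hits, gap) {
  key <- paste(hits$scaffold, hits$strand)
  out <- integer(nrow(hits))
  cl <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(hits$start[idx])]
    last_end <- -Inf
    for (i in idx) {
      if (hits$start[i] - last_end - 1L > gap) cl <- cl + 1L
      out[i] <- cl
      last_end <- max(last_end, hits$end[i])
    }
  }
  out
}

#' Excise and fold candidate hairpin precursors
#'
#' Hits from unannotated tags are clustered into loci (gap at most
#' `criteria$cluster_gap`); for each locus, precursor windows extending
#' `criteria$flank_length` beyond the dominant (highest-count) tag on one
#' side and a ladder of extensions up to `criteria$max_window_ext` on the
#' other (mature tried on both arms) are excised, folded, and reduced to
#' duplex metrics; the best window per locus (most criteria passed, then
#' most paired bases, then lowest MFE) becomes the locus's candidate.
#'
#' @param genome named character vector of scaffolds.
#' @param hits data.frame from [map_tags()] restricted to unannotated tags.
#' @param tags data.frame from [collapse_tags()] (for tag counts).
#' @param criteria a [novel_criteria()] object.
#' @return list of hairpin candidates; each is a list with locus
#'   coordinates (`scaffold`, `start`, `end`, `strand`, `clipped`), the
#'   RNA `precursor`, `structure`, `mfe`, mature tag info (`tag_id`,
#'   `mature_seq`, `read_count`, `mature_start`/`mature_end` within the
#'   precursor) and `metrics`.
#' @export
excise_candidates <- function(genome, hits, tags, criteria = novel_criteria()) {
  if (nrow(hits) == 0L) return(list())
  counts <- setNames(tags$count, tags$tag_id)
  hits$count <- counts[hits$tag_id]
  hits <- hits[!is.na(hits$count), , drop = FALSE]
  if (nrow(hits) == 0L) return(list())
  hits$cluster <- cluster_hits(hits, criteria$cluster_gap)

  flank <- criteria$flank_length
  exts <- unique(pmin(criteria$max_window_ext,
                      c(40L, 60L, 90L, 130L, 180L, 250L, criteria$max_window_ext)))
  specs <- list(); keys <- list()
  for (cl in unique(hits$cluster)) {
    h <- hits[hits$cluster == cl, , drop = FALSE]
    dom <- h[order(-h$count, h$start), , drop = FALSE][1, ]
    # a locus whose dominant tag lacks read support can never be emitted;
    # skip it before the (costly) folding stage
    if (dom$count < criteria$min_read_count) next
    slen <- nchar(genome[[dom$scaffold]])
    for (ext in exts) {
      for (arm in c("5p", "3p")) {
        ws <- if (arm == "5p") dom$start - flank else dom$start - ext
        we <- if (arm == "5p") dom$end + ext else dom$end + flank
        cs <- max(1L, ws); ce <- min(slen, we)
        specs[[length(specs) + 1L]] <- list(
          cluster = cl, scaffold = dom$scaffold, start = cs, end = ce,
          strand = dom$strand, clipped = (cs != ws || ce != we),
          tag_id = dom$tag_id, mature_seq = dom$tag_sequence,
          read_count = dom$count, hstart = dom$start, hend = dom$end)
      }
    }
  }
  specs <- unique_window_specs(specs)
  seqs <- vapply(specs, function(w) {
    s <- substr(genome[[w$scaffold]], w$start, w$end)
    if (w$strand == "-") s <- revcomp(s) else s
  }, character(1))
  folded <- fold_rna(dna_to_rna(seqs))

  # pass 1: locate the miRNA/miRNA* duplex in each search window, then trim
  # the precursor to duplex +/- flank so the judged object (and its MFE) is
  # independent of the search-window size
  trimmed <- list()
  for (i in seq_along(specs)) {
    w <- specs[[i]]
    if (w$strand == "+") {
      mstart <- w$hstart - w$start + 1L
    } else {
      mstart <- w$end - w$hend + 1L
    }
    mend <- mstart + (w$hend - w$hstart)
    if (mstart < 1L || mend > nchar(seqs[i])) next
    m <- duplex_metrics(folded$structure[i], mstart, mend)
    if (is.null(m)) next
    # duplex bounds in window coordinates, from the metric flanks
    duplex_lo <- m$flank5 + 1L
    duplex_hi <- nchar(seqs[i]) - m$flank3
    if (w$strand == "+") {
      t_ws <- w$start + duplex_lo - 1L - flank
      t_we <- w$start + duplex_hi - 1L + flank
    } else {
      t_ws <- w$end - duplex_hi + 1L - flank
      t_we <- w$end - duplex_lo + 1L + flank
    }
    slen <- nchar(genome[[w$scaffold]])
    cs <- max(1L, t_ws); ce <- min(slen, t_we)
    trimmed[[paste(w$cluster, cs, ce, sep = ":")]] <- list(
      cluster = w$cluster, scaffold = w$scaffold, start = cs, end = ce,
      strand = w$strand, clipped = (cs != t_ws || ce != t_we),
      tag_id = w$tag_id, mature_seq = w$mature_seq, read_count = w$read_count,
      hstart = w$hstart, hend = w$hend)
  }
  if (length(trimmed) == 0L) return(list())
  trimmed <- unname(trimmed)
  tseqs <- vapply(trimmed, function(w) {
    s <- substr(genome[[w$scaffold]], w$start, w$end)
    if (w$strand == "-") revcomp(s) else s
  }, character(1))
  tfold <- fold_rna(dna_to_rna(tseqs))

  # pass 2: judge the trimmed precursors and keep the best per locus
  # (most duplex pairs, then most criteria passed, then tightest)
  best <- list()
  for (i in seq_along(trimmed)) {
    w <- trimmed[[i]]
    if (w$strand == "+") {
      mstart <- w$hstart - w$start + 1L
    } else {
      mstart <- w$end - w$hend + 1L
    }
    mend <- mstart + (w$hend - w$hstart)
    if (mstart < 1L || mend > nchar(tseqs[i])) next
    cand <- list(scaffold = w$scaffold, start = w$start, end = w$end,
                 strand = w$strand, clipped = w$clipped, tag_id = w$tag_id,
                 mature_seq = dna_to_rna(w$mature_seq), read_count = w$read_count,
                 precursor = tfold$sequence[i], structure = tfold$structure[i],
                 mfe = tfold$mfe[i], mature_start = mstart, mature_end = mend)
    cand$metrics <- duplex_metrics(cand$structure, mstart, mend)
    if (is.null(cand$metrics)) next
    ev <- apply_novel_criteria(cand, cand$metrics, w$read_count, criteria)
    score <- c(cand$metrics$paired_bases, sum(ev$report$pass),
               -(w$end - w$start))
    key <- as.character(w$cluster)
    if (is.null(best[[key]]) || better_window(score, best[[key]]$score)) {
      cand$score <- score
      best[[key]] <- cand
    }
  }
  unname(best[order(vapply(best, function(b) sprintf("%s:%010d", b$scaffold, b$start), character(1)))])
}

unique_window_specs <- function(specs) {
  keys <- vapply(specs, function(w) paste(w$cluster, w$start, w$end), character(1))
  specs[!duplicated(keys)]
}

better_window <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Predict novel miRNAs from unannotated tags
#'
#' Composition of excision, folding, duplex metrics, the nine criteria and
#' the read-support floor. Emitted novel miRNAs carry zero-padded `m####`
#' ids assigned in (scaffold, start) order.
#'
#' @param genome named character vector of scaffolds.
#' @param tags data.frame from [collapse_tags()].
#' @param hits data.frame from [map_tags()] restricted to unannotated tags.
#' @param criteria a [novel_criteria()] object.
#' @return list with `novel` (data.frame of emitted miRNAs), `candidates`
#'   (all per-locus candidates) and `evaluations` (per-candidate criterion
#'   reports, parallel to `candidates`).
#' @export
predict_novel <- function(genome, tags, hits, criteria = novel_criteria()) {
  cands <- excise_candidates(genome, hits, tags, criteria)
  copies <- table(hits$tag_id)
  evals <- vector("list", length(cands))
  emit <- list()
  for (i in seq_along(cands)) {
    cand <- cands[[i]]
    n_cop <- as.integer(copies[cand$tag_id])
    ev <- apply_novel_criteria(cand, cand$metrics, cand$read_count, criteria, n_cop)
    ev$supported <- cand$read_count >= criteria$min_read_count
    evals[[i]] <- ev
    if (ev$overall && ev$supported) {
      m <- cand$metrics
      star <- substr(cand$precursor, m$star_start, m$star_end)
      emit[[length(emit) + 1L]] <- data.frame(
        scaffold = cand$scaffold, start = cand$start, end = cand$end,
        strand = cand$strand, mature_sequence = cand$mature_seq,
        star_sequence = star, precursor = cand$precursor,
        structure = cand$structure, mfe = cand$mfe,
        precursor_length = nchar(cand$precursor),
        mature_start = cand$mature_start, mature_end = cand$mature_end,
        star_start = m$star_start, star_end = m$star_end,
        read_count = cand$read_count, stringsAsFactors = FALSE)
    }
  }
  novel <- if (length(emit) > 0L) do.call(rbind, emit) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               strand = character(), mature_sequence = character(),
               star_sequence = character(), precursor = character(),
               structure = character(), mfe = numeric(),
               precursor_length = integer(), mature_start = integer(),
               mature_end = integer(), star_start = integer(),
               star_end = integer(), read_count = integer(),
               stringsAsFactors = FALSE)
  if (nrow(novel) > 1L) {
    # a hairpin whose arms are near-reverse-complements can be rediscovered
    # from the opposite strand; keep the better-supported of overlapping
    # opposite-strand twins
    ord <- order(-novel$read_count, novel$mfe)
    keep <- logical(nrow(novel))
    for (i in ord) {
      kept <- which(keep)
      clash <- any(novel$scaffold[kept] == novel$scaffold[i] &
                     novel$start[kept] <= novel$end[i] &
                     novel$end[kept] >= novel$start[i] &
                     novel$strand[kept] != novel$strand[i])
      if (!clash) keep[i] <- TRUE
    }
    novel <- novel[keep, , drop = FALSE]
  }
  if (nrow(novel) > 0L) {
    novel <- novel[order(novel$scaffold, novel$start), , drop = FALSE]
    novel <- cbind(id = sprintf("m%04d", seq_len(nrow(novel))), novel,
                   stringsAsFactors = FALSE)
    rownames(novel) <- NULL
  } else {
    novel <- cbind(id = character(0), novel)
  }
  list(novel = novel, candidates = cands, evaluations = evals)
}
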