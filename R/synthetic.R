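# Synthetic-data generator: genomes with annotated ncRNA/exon/intron/repeat
# features, planted miRNA hairpins (criterion-satisfying and single-violation
# decoys), and the truth tables recovery tests are scored against. Every
# planted object is verified by the package's own downstream predicates
# (fold_rna / duplex_metrics / apply_novel_criteria) before it is emitted;
# generation is a pure function of the spec and its seed.

FEATURE_LENGTHS <- c(rRNA = 1500L, tRNA = 80L, snRNA = 150L, snoRNA = 120L,
                     exon = 300L, intron = 500L, "repeat" = 400L)

#' Simulation specification
#'
#' Defines the synthetic study conditions: genome size, planted hairpin
#' composition, library depth, read-class fractions (emulating the published
#' contaminant accounting and annotation composition), the 21/24-nt length
#' modes and the 5'-U first-nucleotide bias.
#'
#' @param seed integer seed; output is fully determined by the spec.
#' @param n_scaffolds,scaffold_length genome shape (nt).
#' @param n_true_hairpins hairpins satisfying all nine criteria.
#' @param decoy_violations criterion names, one decoy planted per entry.
#' @param read_depth total raw reads of the sRNA library.
#' @param class_fractions named fractions over read classes (contaminant
#'   classes, annotated ncRNA/exon/intron/repeat fragments, known miRNAs,
#'   planted mature/star reads and unannotated background); must sum to 1.
#'   Defaults follow the published library composition: ~0.5% low quality,
#'   0.04/0.02/0.18% adapter artefacts, 2.26% short, rRNA 14%, tRNA 4.4%,
#'   known miRNA 21.9%, and an unannotated remainder near 50%.
#' @param length_mode_fractions fractions of background read lengths, peaked
#'   at 21 nt with a secondary 24-nt mode.
#' @param first_nt_u_bias probability that a planted mature miRNA starts
#'   with U.
#' @param feature_counts features planted per genome, by type.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_scaffolds = 3L, scaffold_length = 50000L,
                            n_true_hairpins = 10L,
                            decoy_violations = NOVEL_CRITERION_NAMES,
                            read_depth = 20000L,
                            class_fractions = c(
                              low_quality = 0.005, adaptor3_null = 0.0004,
                              insert_null = 0.0002, adaptor5_contaminant = 0.0018,
                              shorter_than_18 = 0.0226, polyA = 0.0001,
                              rRNA = 0.1405, tRNA = 0.0442, snRNA = 0.0007,
                              snoRNA = 0.0002, exon = 0.0459, intron = 0.0501,
                              "repeat" = 0.01, known_mirna = 0.2192,
                              novel_mature = 0.04, novel_star = 0.004,
                              background = NA),
                            length_mode_fractions = c(
                              "18" = 0.02, "19" = 0.02, "20" = 0.05, "21" = 0.38,
                              "22" = 0.08, "23" = 0.06, "24" = 0.30, "25" = 0.04,
                              "26" = 0.02, "27" = 0.01, "28" = 0.01, "29" = 0.005,
                              "30" = 0.005),
                            first_nt_u_bias = 0.8,
                            feature_counts = c(rRNA = 2L, tRNA = 4L, snRNA = 2L,
                                               snoRNA = 2L, exon = 6L, intron = 6L,
                                               "repeat" = 3L)) {
  seed <- stopifnot_scalar_int(seed, "seed")
  n_scaffolds <- stopifnot_scalar_int(n_scaffolds, "n_scaffolds", 1L)
  scaffold_length <- stopifnot_scalar_int(scaffold_length, "scaffold_length", 1000L)
  if (is.na(class_fractions[["background"]])) {
    class_fractions[["background"]] <- 1 - sum(class_fractions, na.rm = TRUE)
  }
  if (any(class_fractions < 0) || any(class_fractions > 1)) {
    stop("class fractions must lie in [0, 1]")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  if (abs(sum(length_mode_fractions) - 1) > 1e-6) {
    stop("length mode fractions must sum to 1")
  }
  stopifnot(first_nt_u_bias >= 0, first_nt_u_bias <= 1,
            all(decoy_violations %in% NOVEL_CRITERION_NAMES))
  structure(list(seed = seed, n_scaffolds = n_scaffolds,
                 scaffold_length = scaffold_length,
                 n_true_hairpins = as.integer(n_true_hairpins),
                 decoy_violations = decoy_violations,
                 read_depth = as.integer(read_depth),
                 class_fractions = class_fractions,
                 length_mode_fractions = length_mode_fractions,
                 first_nt_u_bias = first_nt_u_bias,
                 feature_counts = feature_counts),
            class = "simulation_spec")
}

#' Generate a synthetic genome with feature annotation
#'
#' Scaffolds are uniform random DNA. Features (rRNA, tRNA, snRNA, snoRNA,
#' exon, intron, repeat) are placed non-overlapping in the first half of
#' each scaffold with random strands; the downstream half of every scaffold
#' is left unannotated so hairpins can be planted there. Deterministic under
#' the spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genome` (named character vector) and `annotation`
#'   (GRanges with `type` and `ID` columns).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  L <- spec$scaffold_length
  genome <- setNames(random_seq(spec$n_scaffolds, L),
                     sprintf("scaffold_%d", seq_len(spec$n_scaffolds)))
  total_features <- sum(spec$feature_counts)
  feat_types <- rep(names(spec$feature_counts), spec$feature_counts)
  # features live in [0.1L, 0.55L]; [1, 0.1L) is unannotated lead-in and
  # (0.55L, L] the unannotated hairpin reserve
  lo <- ceiling(0.10 * L); hi <- floor(0.55 * L)
  need <- sum(FEATURE_LENGTHS[feat_types]) + 50L * (total_features + 1L)
  if (total_features > 0L && need > (hi - lo + 1L) * spec$n_scaffolds) {
    stop("scaffold_length too small to host the requested features")
  }
  rows <- list()
  if (total_features > 0L) {
    scaf_of <- sort(rep_len(seq_len(spec$n_scaffolds), total_features))
    feat_types <- sample(feat_types)
    for (s in unique(scaf_of)) {
      idx <- which(scaf_of == s)
      cursor <- lo
      for (i in idx) {
        flen <- FEATURE_LENGTHS[[feat_types[i]]]
        gap <- sample(30:80, 1)
        start <- cursor + gap
        if (start + flen - 1L > hi) stop("scaffold_length too small to host the requested features")
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = names(genome)[s], start = start, end = start + flen - 1L,
          strand = sample(c("+", "-"), 1), type = feat_types[i],
          stringsAsFactors = FALSE)
        cursor <- start + flen - 1L
      }
    }
  }
  if (length(rows) > 0L) {
    df <- do.call(rbind, rows)
    ann <- GenomicRanges::GRanges(df$scaffold, IRanges::IRanges(df$start, df$end),
                                  strand = df$strand)
    ann$type <- df$type
    ann$ID <- sprintf("%s_%02d", df$type, seq_len(nrow(df)))
  } else {
    ann <- GenomicRanges::GRanges()
    ann$type <- character(0)
    ann$ID <- character(0)
  }
  list(genome = genome, annotation = ann)
}

#' Generate a miRBase-style known mature miRNA database
#'
#' Synthetic stand-in for a mature miRNA reference: `n` random mature
#' sequences with plant-style ids (`ppe-miR0xx`), 5'-U biased.
#'
#' @param n number of miRNAs.
#' @param seed integer seed.
#' @param u_bias probability of a U first nucleotide.
#' @return named character vector (DNA alphabet).
#' @export
simulate_known_db <- function(n = 20L, seed = 1L, u_bias = 0.8) {
  set.seed(seed + 211L)
  seqs <- vapply(seq_len(n), function(i) {
    repeat {
      s <- sample_mature(21L, u_bias = u_bias)
      if (clean_insert_ok(s)) return(s)
    }
  }, character(1))
  setNames(seqs, sprintf("ppe-miR%03d", seq_len(n)))
}

sample_mature <- function(len, u_bias = 0.8, gc = 0.5, alphabet = BASES) {
  p <- if (identical(alphabet, BASES)) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
       else rep(1 / length(alphabet), length(alphabet))
  s <- sample(alphabet, len, replace = TRUE, prob = p)
  if (runif(1) < u_bias && "T" %in% alphabet) s[1] <- "T"
  paste(s, collapse = "")
}

# --- hairpin construction -------------------------------------------------

# star partner index of mature position i for a mature of length L
star_partner_idx <- function(i, L) L - i + 1L

# build a star arm (5'->3' DNA) from a mature arm with controlled defects
build_star <- function(mature, wobbles = integer(0), mismatches = integer(0),
                       delete = integer(0), insert_at = NA_integer_,
                       insert_len = 0L) {
  L <- nchar(mature)
  mat <- strsplit(mature, "", fixed = TRUE)[[1]]
  star <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
  for (i in wobbles) {
    j <- star_partner_idx(i, L)
    star[j] <- switch(mat[i], G = "T", T = "G",
                      stop("wobble requires mature G or T"))
  }
  for (i in mismatches) {
    j <- star_partner_idx(i, L)
    star[j] <- switch(mat[i], A = "A", C = "C", G = "G", T = "C")
  }
  if (length(delete) > 0L) {
    star <- star[-vapply(delete, star_partner_idx, integer(1), L = L)]
  }
  if (!is.na(insert_at) && insert_len > 0L) {
    ins <- sample(c("A", "C"), insert_len, replace = TRUE)
    star <- append(star, ins, after = insert_at)
  }
  paste(star, collapse = "")
}

pick_wobble_sites <- function(mature, k = 2L) {
  mat <- strsplit(mature, "", fixed = TRUE)[[1]]
  L <- length(mat)
  elig <- which(mat %in% c("G", "T"))
  elig <- elig[elig >= 4L & elig <= L - 3L]
  if (length(elig) < k) return(NULL)
  repeat {
    s <- sort(sample(elig, k))
    if (k < 2L || min(diff(s)) > 1L) return(s)
  }
}

pick_spread_sites <- function(L, k, lo = 4L) {
  # k interior, pairwise non-adjacent positions
  cand <- seq(lo, L - 3L)
  for (try in 1:50) {
    s <- sort(sample(cand, k))
    if (k < 2L || min(diff(s)) > 1L) return(s)
  }
  NULL
}

# construct one hairpin of the requested kind; returns the precursor pieces
# (flank5 may be shortened for the flank decoy) or NULL if sampling failed
construct_hairpin <- function(kind, u_bias) {
  loop_len <- sample(8:14, 1)
  flank5 <- random_seq(1, 20L); flank3 <- random_seq(1, 20L)
  mk <- function(mature, star) {
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
    list(flank5 = flank5, mature = mature, loop = loop, star = star,
         flank3 = flank3)
  }
  if (kind %in% c("pass", "flank", "max_ref_copies", "loop_space")) {
    len <- sample(c(20L, 21L, 22L), 1, prob = c(0.2, 0.6, 0.2))
    mature <- sample_mature(len, u_bias, gc = 0.55)
    w <- pick_wobble_sites(mature)
    if (is.null(w)) return(NULL)
    h <- mk(mature, build_star(mature, wobbles = w))
    if (kind == "loop_space") {
      h$loop <- random_seq(1, 310L)
    }
    return(h)
  }
  if (kind == "mature_len" || kind == "ref_len") {
    len <- if (kind == "mature_len") 26L else 24L
    mature <- sample_mature(len, u_bias, gc = 0.55)
    w <- pick_wobble_sites(mature)
    if (is.null(w)) return(NULL)
    return(mk(mature, build_star(mature, wobbles = w)))
  }
  if (kind == "mfe") {
    # a weak but well-formed stem: low-GC 20-mer with four isolated
    # mismatches folds into a clean duplex whose energy straddles -18
    mature <- sample_mature(20L, u_bias, gc = 0.35)
    mm <- pick_spread_sites(20L, 4L)
    if (is.null(mm)) return(NULL)
    return(mk(mature, build_star(mature, mismatches = mm)))
  }
  if (kind == "min_paired") {
    mature <- sample_mature(21L, u_bias, gc = 0.65)
    mm <- pick_spread_sites(21L, 6L)
    if (is.null(mm)) return(NULL)
    return(mk(mature, build_star(mature, mismatches = mm)))
  }
  if (kind == "max_bulge") {
    mature <- sample_mature(21L, u_bias, gc = 0.6)
    return(mk(mature, build_star(mature, delete = 9:13, insert_at = 3L,
                                 insert_len = 5L)))
  }
  if (kind == "max_asymmetry") {
    mature <- sample_mature(21L, u_bias, gc = 0.6)
    return(mk(mature, build_star(mature, delete = c(6:8, 13:14))))
  }
  stop("unknown hairpin kind: ", kind)
}

hairpin_sequence <- function(h) {
  paste0(h$flank5, h$mature, h$loop, h$star, h$flank3)
}

# fold the naked precursor and evaluate the nine criteria; returns the
# evaluation or NULL if the duplex is undefined
evaluate_precursor <- function(h, criteria) {
  pre <- hairpin_sequence(h)
  ms <- nchar(h$flank5) + 1L
  me <- ms + nchar(h$mature) - 1L
  fr <- fold_rna(dna_to_rna(pre))
  m <- duplex_metrics(fr$structure, ms, me)
  ev <- apply_novel_criteria(list(mfe = fr$mfe, mature_start = ms, mature_end = me),
                             m, criteria = criteria)
  ev$metrics <- m
  ev
}

# expected pass-vector for a planted hairpin kind (TRUE = criterion passes);
# a 26-nt mature necessarily fails both length windows
expected_pass_vector <- function(kind) {
  pass <- setNames(rep(TRUE, length(NOVEL_CRITERION_NAMES)), NOVEL_CRITERION_NAMES)
  if (kind == "pass") return(pass)
  pass[kind] <- FALSE
  if (kind == "mature_len") pass["ref_len"] <- FALSE
  pass
}

matches_expectation <- function(ev, kind) {
  got <- setNames(ev$report$pass, ev$report$criterion)
  identical(unname(got[NOVEL_CRITERION_NAMES]),
            unname(expected_pass_vector(kind)[NOVEL_CRITERION_NAMES]))
}

#' Plant criterion-satisfying hairpins and single-violation decoys
#'
#' Inserts `spec$n_true_hairpins` hairpins that satisfy all nine criteria
#' and one decoy per entry of `spec$decoy_violations`, each violating only
#' its named criterion (a 26-nt mature necessarily fails both length
#' windows). Construction samples a near-perfect stem (two G:U wobbles, so
#' the two arms are not exact reverse complements) and introduces controlled
#' mismatches, bulges and asymmetric loops; every hairpin is verified by
#' folding and the criteria check before insertion, with bounded resampling,
#' and again through the excision path after insertion. The `flank` decoy is
#' planted at a scaffold edge so its precursor window is clipped; the
#' `max_ref_copies` decoy's mature sequence is additionally copied to 21
#' extra genomic loci.
#'
#' @param genome_ann list from [generate_genome()].
#' @param spec a [simulation_spec()].
#' @param criteria a [novel_criteria()] object.
#' @param max_attempts resampling bound per hairpin.
#' @return list with the modified `genome`, the `annotation` (unchanged) and
#'   `truth` (data.frame: hairpin_id, label, violated_criterion, scaffold,
#'   start, end, strand, mature_seq, star_seq, genomic mature coordinates).
#' @export
plant_hairpins <- function(genome_ann, spec, criteria = novel_criteria(),
                           max_attempts = 120L) {
  set.seed(spec$seed + 1L)
  genome <- genome_ann$genome
  L <- spec$scaffold_length
  reserve_lo <- floor(0.62 * L); reserve_hi <- L - 600L
  slot_step <- 1300L
  slots <- list()
  for (s in names(genome)) {
    starts <- seq(reserve_lo, reserve_hi - 500L, by = slot_step)
    for (st in starts) slots[[length(slots) + 1L]] <- list(scaffold = s, start = st)
  }
  kinds <- c(rep("pass", spec$n_true_hairpins), spec$decoy_violations)
  if (length(slots) < length(kinds)) {
    stop("scaffold_length too small to host the requested hairpins")
  }
  slots <- slots[seq_along(kinds)]
  truth <- list(); used_matures <- character(0)
  copy_jobs <- list()
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    planted <- FALSE
    for (attempt in seq_len(max_attempts)) {
      h <- construct_hairpin(kind, spec$first_nt_u_bias)
      if (is.null(h)) next
      if (h$mature %in% used_matures) next
      if (!clean_insert_ok(h$mature) || !clean_insert_ok(h$star)) next
      if (any(vapply(genome, function(g) grepl(h$mature, g, fixed = TRUE) ||
                       grepl(revcomp(h$mature), g, fixed = TRUE), logical(1)))) next
      # the flank decoy is structurally sound (checked with full flanks) and
      # only violates its criterion through scaffold-edge clipping; the
      # copy-number decoy only through the extra loci planted afterwards
      pre_kind <- if (kind %in% c("flank", "max_ref_copies")) "pass" else kind
      post_kind <- if (kind == "max_ref_copies") "pass" else kind
      ev <- evaluate_precursor(h, criteria)
      if (!matches_expectation(ev, pre_kind)) next
      if (kind == "flank") h$flank5 <- substr(h$flank5, 1L, 5L)

      pre <- hairpin_sequence(h)
      strand <- if (kind %in% c("flank", "loop_space")) "+" else sample(c("+", "-"), 1)
      ins <- if (strand == "+") pre else revcomp(pre)
      if (kind == "flank") {
        scaf <- names(genome)[1]; pos <- 1L
      } else {
        scaf <- slots[[k]]$scaffold; pos <- slots[[k]]$start
      }
      g <- genome[[scaf]]
      genome[[scaf]] <- paste0(substr(g, 1L, pos - 1L), ins,
                               substr(g, pos + nchar(ins), nchar(g)))
      # verify through the excision path on the modified genome
      tags <- data.frame(tag_id = "probe", sequence = h$mature, count = 10L)
      hits <- map_tags(tags, genome[scaf])
      cands <- excise_candidates(genome[scaf], hits, tags, criteria)
      ok <- FALSE
      if (length(cands) >= 1L) {
        cand <- cands[[1]]
        ev2 <- apply_novel_criteria(cand, cand$metrics, 10L, criteria)
        ok <- matches_expectation(ev2, post_kind) && cand$strand == strand
      }
      if (!ok) {
        genome[[scaf]] <- g  # roll back and resample
        next
      }
      if (strand == "+") {
        m_start <- pos + nchar(h$flank5); m_end <- m_start + nchar(h$mature) - 1L
      } else {
        m_end <- pos + nchar(ins) - nchar(h$flank5) - 1L
        m_start <- m_end - nchar(h$mature) + 1L
      }
      truth[[length(truth) + 1L]] <- data.frame(
        hairpin_id = sprintf("h%02d", k),
        label = if (kind == "pass") "pass" else "fail",
        violated_criterion = if (kind == "pass") NA_character_ else kind,
        scaffold = scaf, start = pos, end = pos + nchar(ins) - 1L,
        strand = strand, mature_seq = h$mature,
        star_seq = h$star, mature_start = m_start, mature_end = m_end,
        stringsAsFactors = FALSE)
      used_matures <- c(used_matures, h$mature)
      if (kind == "max_ref_copies") {
        copy_jobs[[length(copy_jobs) + 1L]] <- h$mature
      }
      planted <- TRUE
      break
    }
    if (!planted) {
      stop(sprintf("failed to construct a '%s' hairpin in %d attempts",
                   kind, max_attempts))
    }
  }
  # extra genomic copies for the copy-number decoy (21 more loci -> 22 total)
  for (mature in unlist(copy_jobs)) {
    scafs <- rep_len(names(genome), 21L)
    for (i in 1:21) {
      off <- reserve_hi + 30L + 60L * (sum(scafs[1:i] == scafs[i]) - 1L)
      g <- genome[[scafs[i]]]
      genome[[scafs[i]]] <- paste0(substr(g, 1L, off - 1L), mature,
                                   substr(g, off + nchar(mature), nchar(g)))
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genome = genome, annotation = genome_ann$annotation, truth = truth)
}
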