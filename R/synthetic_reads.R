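# Read-level simulators: the adapter-ligated sRNA library with its
# contaminant classes and truth sidecar, the transcriptome with planted
# target sites, the degradome with planted cleavage peaks, and Ct tables
# for relative-quantification testing.

#' Default small-RNA library adapters
#'
#' TruSeq-style 3' and 5' small-RNA adapters used by the simulator and as
#' the [filter_reads()] defaults.
#' @export
DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"

#' @rdname DEFAULT_ADAPTER3
#' @export
DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

sample_lengths <- function(n, fracs) {
  as.integer(sample(names(fracs), n, replace = TRUE, prob = fracs))
}

random_non_adapter <- function(len, adapter3, adapter5, seed5 = 8L) {
  a5 <- substr(adapter5, nchar(adapter5) - seed5 + 1L, nchar(adapter5))
  repeat {
    s <- random_seq(1, len)
    if (is.na(find_adapter(s, adapter3)) && !startsWith(s, a5)) return(s)
  }
}

# TRUE when an insert will survive adapter trimming intact: the first
# 3'-adapter seed in insert+adapter sits exactly at the ligation junction
# (no seed inside the insert or straddling the junction), and the insert
# does not begin with the 5'-adapter suffix
clean_insert_ok <- function(s, adapter3 = DEFAULT_ADAPTER3,
                            adapter5 = DEFAULT_ADAPTER5) {
  seed <- substr(adapter3, 1L, 6L)
  first <- regexpr(seed, paste0(s, seed), fixed = TRUE)
  first == nchar(s) + 1L &
    !startsWith(s, substr(adapter5, nchar(adapter5) - 7L, nchar(adapter5)))
}

random_clean_insert <- function(len) {
  repeat {
    s <- random_seq(1, len)
    if (clean_insert_ok(s)) return(s)
  }
}

feature_fragment <- function(genome, annotation, type, len, antisense = FALSE,
                             max_tries = 50L) {
  idx <- which(as.character(annotation$type) == type)
  if (length(idx) == 0L) return(NULL)
  for (t in seq_len(max_tries)) {
    f <- annotation[idx[sample.int(length(idx), 1L)]]
    flen <- BiocGenerics::width(f)
    l <- min(len, flen)
    off <- sample.int(flen - l + 1L, 1L)
    s <- substr(genome[[as.character(GenomicRanges::seqnames(f))]],
                BiocGenerics::start(f) + off - 1L,
                BiocGenerics::start(f) + off + l - 2L)
    sense_seq <- if (as.character(BiocGenerics::strand(f)) == "-") revcomp(s) else s
    out <- if (antisense) revcomp(sense_seq) else sense_seq
    if (clean_insert_ok(out)) return(out)
  }
  stop("could not sample an adapter-free feature fragment")
}

#' Simulate an adapter-ligated small-RNA library with truth sidecar
#'
#' Draws read classes from the spec's class fractions (multinomial at the
#' requested depth), builds each read as insert + 3' adapter with constant
#' high quality (low-quality reads get a failing quality string), and
#' records every read's true class. Planted hairpins receive a deterministic
#' equal split of the mature-read budget so every hairpin clears the
#' read-support floor at realistic depths; star reads are rarer by the spec
#' fraction.
#'
#' @param planted result of [plant_hairpins()] (genome + annotation + truth).
#' @param spec a [simulation_spec()].
#' @param known_db named character vector of known mature miRNAs
#'   (e.g. [simulate_known_db()]).
#' @return list with `reads` (data.frame read_id/sequence/quality) and
#'   `truth` (data.frame read_id/class/source_id), plus the `adapters` used.
#' @export
simulate_srna_library <- function(planted, spec, known_db = simulate_known_db()) {
  set.seed(spec$seed + 2L)
  n <- spec$read_depth
  classes <- names(spec$class_fractions)
  counts <- if (n > 0L) {
    stats::setNames(as.integer(stats::rmultinom(1, n, spec$class_fractions)), classes)
  } else stats::setNames(integer(length(classes)), classes)
  ann_types <- unique(as.character(planted$annotation$type))
  # reallocate fragment classes with no features to plant to background
  for (cl in intersect(c("rRNA", "tRNA", "snRNA", "snoRNA", "exon", "intron", "repeat"),
                       classes)) {
    if (counts[[cl]] > 0L && !(cl %in% ann_types)) {
      counts[["background"]] <- counts[["background"]] + counts[[cl]]
      counts[[cl]] <- 0L
    }
  }
  a3 <- DEFAULT_ADAPTER3; a5 <- DEFAULT_ADAPTER5
  hairpins <- planted$truth
  inserts <- character(0); cls <- character(0); src <- character(0)
  add <- function(seqs, class, source) {
    inserts <<- c(inserts, seqs)
    cls <<- c(cls, rep(class, length.out = length(seqs)))
    src <<- c(src, rep(source, length.out = length(seqs)))
  }
  equal_split <- function(total, k) {
    if (k == 0L) return(integer(0))
    base <- total %/% k
    extra <- total %% k
    base + c(rep(1L, extra), rep(0L, k - extra))
  }
  for (cl in classes) {
    k <- counts[[cl]]
    if (k == 0L) next
    switch(cl,
      low_quality = add(random_seq(k, 22L), cl, "synthetic"),
      adaptor3_null = add(vapply(seq_len(k), function(i)
        random_non_adapter(35L, a3, a5), character(1)), cl, "synthetic"),
      insert_null = add(rep("", k), cl, "synthetic"),
      adaptor5_contaminant = add(paste0(substr(a5, nchar(a5) - 7L, nchar(a5)),
                                        random_seq(k, 21L)), cl, "synthetic"),
      shorter_than_18 = add(vapply(seq_len(k), function(i)
        random_clean_insert(10L), character(1)), cl, "synthetic"),
      polyA = add(rep(strrep("A", 25L), k), cl, "synthetic"),
      rRNA = , tRNA = , snRNA = , snoRNA = {
        lens <- pmax(18L, pmin(30L, sample_lengths(k, spec$length_mode_fractions)))
        add(vapply(lens, function(l)
          feature_fragment(planted$genome, planted$annotation, cl, l), character(1)),
          cl, cl)
      },
      exon = , intron = {
        lens <- pmax(18L, pmin(30L, sample_lengths(k, spec$length_mode_fractions)))
        anti <- runif(k) < 0.3
        add(vapply(seq_len(k), function(i)
          feature_fragment(planted$genome, planted$annotation, cl, lens[i], anti[i]),
          character(1)), paste0(cl, ifelse(anti, "_antisense", "_sense")), cl)
      },
      "repeat" = {
        lens <- pmax(18L, pmin(30L, sample_lengths(k, spec$length_mode_fractions)))
        add(vapply(lens, function(l)
          feature_fragment(planted$genome, planted$annotation, "repeat", l),
          character(1)), "repeat", "repeat")
      },
      known_mirna = {
        ids <- sample(names(known_db), k, replace = TRUE)
        add(unname(known_db[ids]), "miRNA", ids)
      },
      novel_mature = {
        per <- equal_split(k, nrow(hairpins))
        for (i in seq_len(nrow(hairpins))) {
          if (per[i] > 0L) add(rep(hairpins$mature_seq[i], per[i]), "novel_mature",
                               hairpins$hairpin_id[i])
        }
      },
      novel_star = {
        # stars of defect-carrying decoys can fall outside the gel-purified
        # 18-30 nt fraction; only size-selected stars yield reads
        elig <- which(nchar(hairpins$star_seq) >= 18L &
                        nchar(hairpins$star_seq) <= 30L)
        per <- equal_split(k, length(elig))
        for (j in seq_along(elig)) {
          i <- elig[j]
          if (per[j] > 0L) add(rep(hairpins$star_seq[i], per[j]), "novel_star",
                               hairpins$hairpin_id[i])
        }
      },
      background = {
        lens <- pmax(18L, pmin(30L, sample_lengths(k, spec$length_mode_fractions)))
        frs <- vapply(lens, function(l)
          background_fragment(planted, l), character(1))
        add(frs, "unannotated", "background")
      },
      stop("unknown read class: ", cl))
  }
  reads <- data.frame(
    read_id = sprintf("r%07d", seq_along(inserts)),
    # every read is insert + 3' adapter, except the 3'-adaptor-null class
    sequence = ifelse(cls == "adaptor3_null", inserts, paste0(inserts, a3)),
    stringsAsFactors = FALSE)
  reads$quality <- strrep("I", nchar(reads$sequence))
  reads$quality[cls == "low_quality"] <- strrep("#", nchar(reads$sequence[cls == "low_quality"]))
  ord <- sample.int(nrow(reads))
  reads <- reads[ord, , drop = FALSE]
  rownames(reads) <- NULL
  truth <- data.frame(read_id = reads$read_id, class = cls[ord], source_id = src[ord],
                      insert = inserts[ord], stringsAsFactors = FALSE)
  list(reads = reads, truth = truth,
       adapters = c(adapter3 = a3, adapter5 = a5))
}

# fragment from unannotated, hairpin-free genome space (sense or antisense)
background_fragment <- function(planted, len, max_tries = 200L) {
  genome <- planted$genome
  ann <- planted$annotation
  hp <- planted$truth
  L <- nchar(genome[[1]])
  reserve_guard <- floor(0.62 * L)  # hairpin reserve + copy region
  for (t in seq_len(max_tries)) {
    scaf <- sample(names(genome), 1L)
    pos <- sample.int(nchar(genome[[scaf]]) - len + 1L, 1L)
    end <- pos + len - 1L
    if (end >= reserve_guard) next
    if (length(ann) > 0L) {
      same <- as.character(GenomicRanges::seqnames(ann)) == scaf
      if (any(same & BiocGenerics::start(ann) <= end & BiocGenerics::end(ann) >= pos)) next
    }
    if (any(hp$scaffold == scaf & hp$start <= end & hp$end >= pos)) next
    s <- substr(genome[[scaf]], pos, end)
    if (runif(1) < 0.5) s <- revcomp(s)
    if (clean_insert_ok(s)) return(s)
  }
  stop("could not sample an unannotated background fragment")
}

# --- transcriptome with planted target sites ------------------------------

mm_partner <- function(base) {
  switch(base, A = "A", C = "C", G = "G", T = "C", U = "C")
}

# site (DNA, 5'->3') realising the requested rule violation against `mirna`
build_target_site <- function(mirna_dna, plan) {
  L <- nchar(mirna_dna)
  mat <- strsplit(mirna_dna, "", fixed = TRUE)[[1]]
  site <- strsplit(revcomp(mirna_dna), "", fixed = TRUE)[[1]]
  mm_at <- function(pos) {
    for (i in pos) site[L - i + 1L] <<- mm_partner(mat[i])
  }
  switch(plan,
    pass = NULL,
    rule1 = mm_at(c(13L, 15L, 17L, 19L, 21L)[c(13L, 15L, 17L, 19L, 21L) <= L]),
    rule2 = mm_at(14:16),
    rule3 = mm_at(5:6),
    rule4 = mm_at(10L),
    rule5 = mm_at(c(3L, 5L, 7L)),
    rule6 = mm_at(c(13L, 15L, 17L, 19L)[c(13L, 15L, 17L, 19L) <= L]),
    stop("unknown site plan: ", plan))
  paste(site, collapse = "")
}

site_plan_expectation <- function(plan, got) {
  pos_rules <- paste0("rule", 1:5)
  if (plan == "pass") return(all(unlist(got[c(pos_rules, "rule6")])))
  if (plan == "rule6") return(all(unlist(got[pos_rules])) && !got$rule6)
  ok_named <- !got[[plan]]
  others <- setdiff(pos_rules, plan)
  ok_named && all(unlist(got[others]))
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' For each miRNA, plants one site per entry of `plans` (a perfect
#' complement plus one single-rule violation per target rule by default),
#' each on its own random transcript, and verifies every site's per-rule
#' labels with [apply_target_rules()] and the duplex energy model before
#' emission. The emitted transcriptome is then rescanned exhaustively and
#' regenerated if any unplanted passing site arose in the background.
#'
#' @param mirnas named character vector of miRNA sequences (DNA or RNA).
#' @param rules a [target_rules()] object.
#' @param seed integer seed.
#' @param plans site plans per miRNA (subset of `pass`, `rule1`..`rule6`).
#' @param transcript_length transcript length (nt).
#' @param n_empty extra transcripts with no planted site.
#' @return list with `transcripts` (named character) and `truth` (data.frame
#'   transcript_id, site_start, site_end, mirna_id, plan, rule1..rule6,
#'   overall).
#' @export
simulate_transcriptome_with_targets <- function(mirnas, rules = target_rules(),
                                                seed = 1L,
                                                plans = c("pass", paste0("rule", 1:6)),
                                                transcript_length = 800L,
                                                n_empty = 2L) {
  stopifnot(all(nchar(mirnas) >= 18L), all(nchar(mirnas) <= 25L))
  set.seed(seed + 3L)
  mirnas_dna <- setNames(rna_to_dna(mirnas), names(mirnas))
  rows <- list(); transcripts <- character(0)
  ti <- 0L
  for (outer_try in 1:25) {
    rows <- list(); transcripts <- character(0); ti <- 0L
    ok_all <- TRUE
    for (mid in names(mirnas_dna)) {
      mseq <- mirnas_dna[[mid]]
      for (plan in plans) {
        site <- build_target_site(mseq, plan)
        planted_ok <- FALSE
        for (try in 1:20) {
          ti_local <- ti + 1L
          tx <- random_seq(1, transcript_length)
          pos <- sample(seq(50L, transcript_length - nchar(site) - 50L), 1L)
          tx <- paste0(substr(tx, 1L, pos - 1L), site,
                       substr(tx, pos + nchar(site), transcript_length))
          st <- align_site(mseq, site)
          ratio <- duplex_mfe(dna_to_rna(mseq), dna_to_rna(site)) /
            perfect_mfe(dna_to_rna(mseq))
          got <- apply_target_rules(st, rules, mfe_ratio = ratio)
          if (!site_plan_expectation(plan, got)) break  # deterministic; no use retrying
          ti <- ti_local
          tid <- sprintf("tx%03d", ti)
          transcripts[tid] <- tx
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = tid, site_start = pos,
            site_end = pos + nchar(site) - 1L, mirna_id = mid, plan = plan,
            rule1 = got$rule1, rule2 = got$rule2, rule3 = got$rule3,
            rule4 = got$rule4, rule5 = got$rule5, rule6 = got$rule6,
            overall = got$overall, stringsAsFactors = FALSE)
          planted_ok <- TRUE
          break
        }
        if (!planted_ok) stop(sprintf("could not realise site plan '%s' for %s",
                                      plan, mid))
      }
    }
    for (e in seq_len(n_empty)) {
      ti <- ti + 1L
      transcripts[sprintf("tx%03d", ti)] <- random_seq(1, transcript_length)
    }
    truth <- do.call(rbind, rows)
    # exhaustive self-check: only the planted passing sites may pass
    found <- scan_transcriptome(mirnas_dna, transcripts, rules)
    want <- truth[truth$overall, c("mirna_id", "transcript_id", "site_start")]
    got_keys <- paste(found$mirna_id, found$transcript_id, found$site_start)
    want_keys <- paste(want$mirna_id, want$transcript_id, want$site_start)
    if (setequal(got_keys, want_keys) && !anyDuplicated(got_keys)) {
      rownames(truth) <- NULL
      return(list(transcripts = transcripts, truth = truth))
    }
    ok_all <- FALSE
  }
  stop("could not generate a collision-free transcriptome")
}

# --- degradome ------------------------------------------------------------

#' Simulate degradome (PARE) reads with planted cleavage peaks
#'
#' For each passing planted target site, generates reads whose 5' end sits
#' exactly at the transcript position pairing miRNA nucleotide 10
#' (site_end - 9), at a per-site peak count; optional uniform background
#' 5' ends are added at `background_rate` per transcript position.
#'
#' @param transcripts named character vector of transcripts.
#' @param target_truth truth data.frame from
#'   [simulate_transcriptome_with_targets()] (its passing rows are cleaved).
#' @param background_rate expected background reads per transcript position.
#' @param seed integer seed.
#' @param peak_range inclusive range the per-site peak count is drawn from.
#' @param read_length degradome read length (nt).
#' @return list with `reads` (data.frame read_id/sequence), `truth`
#'   (transcript_id, mirna_id, cleavage_position, expected_peak_count).
#' @export
simulate_degradome <- function(transcripts, target_truth, background_rate = 0,
                               seed = 1L, peak_range = c(20L, 60L),
                               read_length = 20L) {
  set.seed(seed + 4L)
  pass <- target_truth[target_truth$overall, , drop = FALSE]
  frs <- character(0); meta <- list()
  for (i in seq_len(nrow(pass))) {
    tid <- pass$transcript_id[i]
    cp <- pass$site_end[i] - 9L
    txlen <- nchar(transcripts[[tid]])
    if (cp < 1L || cp > txlen) stop("cleavage position outside transcript")
    rng <- seq.int(peak_range[1], peak_range[2])
    cnt <- rng[sample.int(length(rng), 1L)]
    frag <- substr(transcripts[[tid]], cp, min(txlen, cp + read_length - 1L))
    frs <- c(frs, rep(frag, cnt))
    meta[[length(meta) + 1L]] <- data.frame(
      transcript_id = tid, mirna_id = pass$mirna_id[i], cleavage_position = cp,
      expected_peak_count = cnt, stringsAsFactors = FALSE)
  }
  if (background_rate > 0) {
    for (tid in names(transcripts)) {
      txlen <- nchar(transcripts[[tid]])
      nbg <- stats::rpois(1, background_rate * txlen)
      if (nbg == 0L) next
      pos <- sample.int(max(1L, txlen - read_length + 1L), nbg, replace = TRUE)
      frs <- c(frs, substr(rep(transcripts[[tid]], nbg), pos,
                           pmin(txlen, pos + read_length - 1L)))
    }
  }
  reads <- data.frame(read_id = sprintf("d%07d", seq_along(frs)),
                      sequence = frs, stringsAsFactors = FALSE)
  truth <- if (length(meta) > 0L) do.call(rbind, meta) else
    data.frame(transcript_id = character(), mirna_id = character(),
               cleavage_position = integer(), expected_peak_count = integer())
  list(reads = reads, truth = truth)
}

# --- qPCR Ct tables -------------------------------------------------------

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target-gene Ct values are `baseline_ct - log2FC + noise`; the reference
#' gene is constant up to noise, so the 2^-ddCt of a sample against the
#' calibrator recovers `2^log2FC` exactly when `noise_sd = 0`.
#'
#' @param effects numeric matrix of true log2 fold changes, genes x samples
#'   (calibrator column usually 0).
#' @param reference_gene reference gene name.
#' @param n_replicates replicates per sample/gene.
#' @param baseline_ct,reference_ct mean Ct of targets (at log2FC 0) and of
#'   the reference gene.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `gene_id`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(effects, reference_gene = "5S_rRNA",
                              n_replicates = 3L, baseline_ct = 24,
                              reference_ct = 16, noise_sd = 0.2, seed = 1L) {
  if (n_replicates < 1L) stop("replicate count must be positive")
  set.seed(seed + 5L)
  samples <- colnames(effects); genes <- rownames(effects)
  rows <- list()
  for (s in samples) {
    for (g in c(genes, reference_gene)) {
      mu <- if (g == reference_gene) reference_ct else baseline_ct - effects[g, s]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene_id = g, replicate = seq_len(n_replicates),
        ct = mu + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
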