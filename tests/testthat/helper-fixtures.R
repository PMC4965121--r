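# Shared fixtures, built once per test run. The planted-genome fixture
# (folding-heavy) is memoised so the recovery, decoy and monotonicity tests
# all reuse one construction.

fx <- new.env(parent = emptyenv())

fixture_spec <- function() {
  simulation_spec(seed = 101L, read_depth = 8000L)
}

fixture_planted <- function() {
  if (is.null(fx$planted)) {
    spec <- fixture_spec()
    fx$planted <- plant_hairpins(generate_genome(spec), spec)
  }
  fx$planted
}

fixture_prediction <- function() {
  if (is.null(fx$prediction)) {
    planted <- fixture_planted()
    truth <- planted$truth
    tags <- data.frame(tag_id = sprintf("t%03d", seq_len(nrow(truth))),
                       sequence = truth$mature_seq, count = 10L,
                       stringsAsFactors = FALSE)
    hits <- map_tags(tags, planted$genome)
    fx$prediction <- list(tags = tags, hits = hits,
                          result = predict_novel(planted$genome, tags, hits))
  }
  fx$prediction
}

fixture_library <- function() {
  if (is.null(fx$library)) {
    fx$library <- simulate_srna_library(fixture_planted(), fixture_spec(),
                                        simulate_known_db(seed = 101L))
  }
  fx$library
}

# independent per-window oracle for target scanning: applies align_site +
# apply_target_rules at every offset of every transcript (a different code
# path from the vectorised scanner), rule 6 via the duplex energies
brute_force_targets <- function(mirnas, transcripts, rules = target_rules()) {
  hits <- list()
  for (mid in names(mirnas)) {
    mseq <- dna_to_rna(mirnas[[mid]])
    L <- nchar(mseq)
    pm <- perfect_mfe(mseq)
    for (tid in names(transcripts)) {
      tx <- dna_to_rna(transcripts[[tid]])
      if (nchar(tx) < L) next
      for (s in seq_len(nchar(tx) - L + 1L)) {
        site <- substr(tx, s, s + L - 1L)
        st <- align_site(mseq, site)
        got <- apply_target_rules(st, rules)
        if (!all(unlist(got[paste0("rule", 1:5)]))) next
        ratio <- duplex_mfe(mseq, site) / pm
        if (ratio >= rules$min_mfe_ratio) {
          hits[[length(hits) + 1L]] <- data.frame(
            mirna_id = mid, transcript_id = tid, site_start = s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer()))
  }
  do.call(rbind, hits)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
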