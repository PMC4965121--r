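# The synthetic-data generator: determinism, contracts, and
# self-verification of planted objects.

test_that("simulation_spec validates its fractions and seed", {
  expect_error(simulation_spec(seed = "a"), "seed")
  expect_error(simulation_spec(first_nt_u_bias = 1.5), "first_nt_u_bias")
  cf <- simulation_spec()$class_fractions
  expect_equal(sum(cf), 1, tolerance = 1e-12)
  bad <- cf; bad[["background"]] <- bad[["background"]] + 0.1
  expect_error(simulation_spec(class_fractions = bad), "sum to 1")
})

test_that("genome generation honours the size contract and is byte-stable", {
  spec <- simulation_spec(seed = 5, n_scaffolds = 2, scaffold_length = 20000)
  ga1 <- generate_genome(spec)
  expect_length(ga1$genome, 2L)
  expect_identical(unname(nchar(ga1$genome)), c(20000L, 20000L))
  ga2 <- generate_genome(spec)
  expect_identical(ga1$genome, ga2$genome)
  expect_identical(as.data.frame(ga1$annotation), as.data.frame(ga2$annotation))
  # zero rRNA features when the count is zero
  fc <- spec$feature_counts; fc[["rRNA"]] <- 0L
  ga3 <- generate_genome(simulation_spec(seed = 5, n_scaffolds = 2,
                                         scaffold_length = 20000,
                                         feature_counts = fc))
  expect_false("rRNA" %in% as.character(ga3$annotation$type))
  expect_error(generate_genome(simulation_spec(scaffold_length = 6000)),
               "too small")
})

test_that("planted hairpins satisfy or violate exactly their labels", {
  planted <- fixture_planted()
  truth <- planted$truth
  expect_identical(sum(truth$label == "pass"), 10L)
  expect_identical(sum(truth$label == "fail"), 9L)
  expect_setequal(truth$violated_criterion[truth$label == "fail"],
                  c("mature_len", "ref_len", "max_ref_copies", "mfe",
                    "loop_space", "min_paired", "max_bulge", "max_asymmetry",
                    "flank"))
  # planted coordinates carry the mature sequence they claim
  for (i in seq_len(nrow(truth))) {
    sub <- substr(planted$genome[[truth$scaffold[i]]],
                  truth$mature_start[i], truth$mature_end[i])
    if (truth$strand[i] == "-") sub <- revcomp(sub)
    expect_identical(sub, truth$mature_seq[i], info = truth$hairpin_id[i])
  }
})

test_that("library simulation conserves depth and records every read class", {
  spec <- fixture_spec()
  lib <- fixture_library()
  expect_identical(nrow(lib$reads), spec$read_depth)
  expect_identical(nrow(lib$truth), spec$read_depth)
  expect_identical(lib$reads$read_id, lib$truth$read_id)
  # multinomial class counts stay within 3 SD of expectation
  counts <- table(lib$truth$class)
  n <- spec$read_depth
  grouped <- c(adaptor3_null = "adaptor3_null", insert_null = "insert_null",
               polyA = "polyA", rRNA = "rRNA", tRNA = "tRNA")
  for (cl in names(grouped)) {
    p <- spec$class_fractions[[cl]]
    got <- if (cl %in% names(counts)) counts[[cl]] else 0L
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1, label = cl)
  }
  # seeded rerun is identical
  lib2 <- simulate_srna_library(fixture_planted(), spec,
                                simulate_known_db(seed = 101L))
  expect_identical(lib$reads, lib2$reads)
  expect_identical(lib$truth, lib2$truth)
})

test_that("depth zero yields an empty but valid library", {
  spec <- simulation_spec(seed = 3, read_depth = 0)
  lib <- simulate_srna_library(fixture_planted(), spec,
                               simulate_known_db(seed = 3))
  expect_identical(nrow(lib$reads), 0L)
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads, tmp)
  expect_identical(nrow(read_fastq(tmp)), 0L)
})

test_that("planted target sites verify their per-rule labels", {
  mirs <- c(mirA = random_dna(1, 21, seed = 71), mirB = random_dna(1, 21, seed = 72))
  tx <- simulate_transcriptome_with_targets(mirs, seed = 73)
  truth <- tx$truth
  # the rule-4 decoy mismatches miRNA position 10 or 11
  r4 <- truth[truth$plan == "rule4", ]
  for (i in seq_len(nrow(r4))) {
    site <- substr(tx$transcripts[[r4$transcript_id[i]]], r4$site_start[i],
                   r4$site_end[i])
    st <- align_site(mirs[[r4$mirna_id[i]]], site)
    expect_true(any(st[10:11] == "MM"))
    expect_false(r4$rule4[i])
  }
  # perfect plants pass everything with score 0
  ps <- truth[truth$plan == "pass", ]
  expect_true(all(ps$overall))
  for (i in seq_len(nrow(ps))) {
    site <- substr(tx$transcripts[[ps$transcript_id[i]]], ps$site_start[i],
                   ps$site_end[i])
    expect_identical(mismatch_score(align_site(mirs[[ps$mirna_id[i]]], site)), 0)
  }
  # every plan violates its named rule
  for (r in paste0("rule", 1:6)) {
    expect_false(any(truth[truth$plan == r, r]))
  }
  # exhaustive rescan finds exactly the planted passing sites
  found <- scan_transcriptome(mirs, tx$transcripts)
  want <- truth[truth$overall, ]
  expect_setequal(paste(found$mirna_id, found$transcript_id, found$site_start),
                  paste(want$mirna_id, want$transcript_id, want$site_start))
})

test_that("degradome simulation is seeded and zero-background is a single spike", {
  tx <- list(transcripts = c(t1 = random_dna(1, 500, seed = 74)),
             truth = data.frame(transcript_id = "t1", site_start = 100L,
                                site_end = 120L, mirna_id = "m", plan = "pass",
                                rule1 = TRUE, rule2 = TRUE, rule3 = TRUE,
                                rule4 = TRUE, rule5 = TRUE, rule6 = TRUE,
                                overall = TRUE, stringsAsFactors = FALSE))
  dg1 <- simulate_degradome(tx$transcripts, tx$truth, 0, seed = 75,
                            peak_range = c(50L, 50L))
  d <- build_density(dg1$reads, tx$transcripts)
  expect_identical(which(d$t1 > 0L), 111L)   # site_end - 9
  expect_identical(d$t1[111], 50L)
  dg2 <- simulate_degradome(tx$transcripts, tx$truth, 0, seed = 75,
                            peak_range = c(50L, 50L))
  expect_identical(dg1$reads, dg2$reads)
})

test_that("Ct simulation obeys its closed forms", {
  eff <- matrix(0, nrow = 2, ncol = 2,
                dimnames = list(c("g1", "g2"), c("cal", "s2")))
  eff["g1", "s2"] <- 1
  ct <- simulate_ct_table(eff, noise_sd = 0, seed = 1)
  res <- ddct(ct, reference_gene = "5S_rRNA", calibrator_sample = "cal")
  expect_equal(res$rel_expression[res$gene_id == "g1" & res$sample == "s2"], 2.0)
  expect_equal(res$rel_expression[res$gene_id == "g2" & res$sample == "s2"], 1.0)
  expect_error(simulate_ct_table(eff, n_replicates = -1), "positive")
})
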