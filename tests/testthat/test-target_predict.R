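# Six-rule target prediction: alignment states, scoring, rule logic,
# scanning and the brute-force oracle.

test_that("align_site classifies WC, wobble and mismatch states", {
  m <- "UUGACAGAAGAAAGAGAGCAC"
  expect_true(all(align_site(m, revcomp(m)) == "WC"))
  # G opposite U is a wobble
  expect_identical(align_site("G", "U"), "GU")
  expect_identical(align_site("U", "G"), "GU")
  expect_identical(align_site("A", "A"), "MM")
  expect_error(align_site("ACGU", "ACGUA"), "length")
})

test_that("the m0233 alignment against the miR156 site scores 2.5", {
  # the published novel m0233 shares the target sites of known miR156;
  # against a perfect miR156 site it differs at positions 1, 12, 15, where
  # position 12 (G over U) is a wobble
  m0233 <- "CUGACAGAAGAGAGUGAGCAC"
  mir156 <- "UUGACAGAAGAAAGAGAGCAC"
  site <- revcomp(mir156)
  st <- align_site(m0233, site)
  expect_identical(which(st == "MM"), c(1L, 15L))
  expect_identical(which(st == "GU"), 12L)
  expect_false(any(st[10:11] == "MM"))
  expect_identical(mismatch_score(st), 2.5)
  got <- apply_target_rules(st, mfe_ratio = duplex_mfe(m0233, site) / perfect_mfe(m0233))
  expect_true(got$overall)
})

test_that("mismatch_score counts G:U as half a mismatch", {
  st <- c(rep("MM", 3), rep("GU", 2), rep("WC", 16))
  expect_identical(mismatch_score(st), 4.0)
  expect_identical(mismatch_score(rep("WC", 21)), 0.0)
  expect_identical(mismatch_score(st, 1:4), 3.5)
})

test_that("the six rules fire independently on constructed alignments", {
  wc <- rep("WC", 21)
  got <- apply_target_rules(wc, mfe_ratio = 1)
  expect_true(all(unlist(got)))

  one_mm <- function(pos) { s <- wc; s[pos] <- "MM"; s }
  got <- apply_target_rules(one_mm(10), mfe_ratio = 1)
  expect_false(got$rule4)
  expect_true(all(unlist(got[c("rule1", "rule2", "rule3", "rule5", "rule6")])))

  # 2 GU in 1-12 plus 2 MM in 13+: rule 5 scores 1.0, rule 1 scores 3.0
  s <- wc; s[c(3, 7)] <- "GU"; s[c(14, 17)] <- "MM"
  expect_identical(mismatch_score(s, 1:12), 1.0)
  expect_identical(mismatch_score(s), 3.0)
  expect_true(apply_target_rules(s, mfe_ratio = 1)$overall)

  # three adjacent mismatches break rule 2 (and rule 3 if 5'-proximal)
  s <- wc; s[14:16] <- "MM"
  got <- apply_target_rules(s, mfe_ratio = 1)
  expect_false(got$rule2); expect_true(got$rule3)
  s <- wc; s[5:6] <- "MM"
  got <- apply_target_rules(s, mfe_ratio = 1)
  expect_true(got$rule2)   # run of 2 allowed...
  expect_false(got$rule3)  # ...but not inside positions 2-12

  # strict adjacency mode lets wobbles extend runs
  s <- wc; s[5] <- "MM"; s[6] <- "GU"
  expect_true(apply_target_rules(s, mfe_ratio = 1)$rule3)
  strict <- target_rules(gu_breaks_adjacency = FALSE)
  expect_false(apply_target_rules(s, strict, mfe_ratio = 1)$rule3)
})

test_that("replacing a wobble by a WC pair never breaks a passing site", {
  set.seed(77)
  for (rep in 1:200) {
    st <- sample(c("WC", "GU", "MM"), 21, replace = TRUE, prob = c(.7, .2, .1))
    if (!any(st == "GU")) next
    before <- apply_target_rules(st)
    if (!isTRUE(before$overall)) next
    st2 <- st
    st2[which(st2 == "GU")[1]] <- "WC"
    after <- apply_target_rules(st2)
    expect_true(after$overall)
  }
})

test_that("scanning equals the per-window oracle and respects identity", {
  mir_set <- c(mirA = random_dna(1, 21, seed = 60), mirB = random_dna(1, 21, seed = 61))
  tx2 <- simulate_transcriptome_with_targets(mir_set, seed = 62)
  found <- scan_transcriptome(mir_set, tx2$transcripts)
  oracle <- brute_force_targets(mir_set, tx2$transcripts)
  expect_identical(paste(found$mirna_id, found$transcript_id, found$site_start),
                   paste(oracle$mirna_id, oracle$transcript_id, oracle$site_start))
  # two miRNAs with identical sequence have identical target lists
  twins <- c(m1 = mir_set[["mirA"]], m2 = mir_set[["mirA"]])
  f2 <- scan_transcriptome(twins, tx2$transcripts)
  k1 <- f2[f2$mirna_id == "m1", c("transcript_id", "site_start")]
  k2 <- f2[f2$mirna_id == "m2", c("transcript_id", "site_start")]
  expect_identical(k1, k2, ignore_attr = TRUE)
  # a miRNA with no complementarity anywhere finds nothing
  f3 <- scan_transcriptome(c(none = strrep("A", 21)),
                           c(t1 = strrep("C", 100)))
  expect_identical(nrow(f3), 0L)
})

test_that("alignment rendering marks pairs and wobbles", {
  m <- "UUGACAGAAGAAAGAGAGCAC"
  lines <- format_target_alignment(m, revcomp(m))
  expect_length(lines, 3)
  expect_identical(substr(lines[2], 11, 31), strrep("|", 21))
})
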