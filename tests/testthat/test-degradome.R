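# Degradome density, cleavage detection and peak categories.

test_that("density counts 5' ends and conserves mapped reads", {
  tx <- c(tx1 = random_dna(1, 800, seed = 41))
  expect_identical(sum(build_density(data.frame(read_id = character(),
                                                sequence = character()),
                                     tx)$tx1), 0L)
  # 50 reads with an identical 5' end at position 565 give density[565] = 50
  frag <- substr(tx[[1]], 565, 584)
  reads <- data.frame(read_id = sprintf("d%02d", 1:50),
                      sequence = rep(frag, 50), stringsAsFactors = FALSE)
  d <- build_density(reads, tx)
  expect_identical(d$tx1[565], 50L)
  expect_identical(sum(d$tx1), 50L)
  # antisense fragments do not count
  d2 <- build_density(data.frame(read_id = "a", sequence = revcomp(frag)), tx)
  expect_identical(sum(d2$tx1), 0L)
})

test_that("peak categories follow the frozen 0-4 definition", {
  d <- integer(100)
  d[10] <- 50L; d[20] <- 8L; d[30] <- 5L; d[40] <- 2L; d[50] <- 1L
  expect_identical(categorize_peak(d, 10), 0L)   # unique maximum
  expect_identical(categorize_peak(d, 20), 2L)   # above the nonzero median (5)
  expect_identical(categorize_peak(d, 30), 3L)   # at the median, > 1
  expect_identical(categorize_peak(d, 40), 3L)   # below the median, > 1
  expect_identical(categorize_peak(d, 50), 4L)   # singleton
  expect_true(is.na(categorize_peak(d, 60)))     # zero: no category
  d[11] <- 50L
  expect_identical(categorize_peak(d, 10), 1L)   # tied maximum
  expect_identical(categorize_peak(d, 11), 1L)
})

test_that("cleavage is called at the position pairing miRNA nucleotide 10", {
  mir <- random_dna(1, 21, seed = 43)
  tx <- random_dna(1, 400, seed = 44)
  pos <- 200L
  tx <- paste0(substr(tx, 1, pos - 1), revcomp(mir), substr(tx, pos + 21, 400))
  txs <- c(t1 = tx)
  targets <- scan_transcriptome(c(mir1 = mir), txs)
  expect_identical(nrow(targets), 1L)
  e <- targets$site_end[1]
  cp <- e - 9L
  frag <- substr(tx, cp, cp + 19L)
  d <- build_density(data.frame(read_id = sprintf("d%d", 1:30),
                                sequence = rep(frag, 30)), txs)
  ev <- detect_cleavage(targets, d)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$cleavage_position, cp)
  expect_identical(ev$peak_count, 30L)
  expect_identical(ev$category, 0L)
  # a peak 3 nt away from the expected position is not an event
  d2 <- build_density(data.frame(read_id = "x",
                                 sequence = substr(tx, cp + 3L, cp + 22L)), txs)
  expect_identical(nrow(detect_cleavage(targets, d2)), 0L)
  # threshold above the peak suppresses the event
  expect_identical(nrow(detect_cleavage(targets, d, min_peak = 31L)), 0L)
})

test_that("t-plot tables mark exactly the detected cleavage positions", {
  tx <- c(t1 = random_dna(1, 300, seed = 45))
  d <- build_density(data.frame(read_id = "r1",
                                sequence = rep(substr(tx[[1]], 100, 119), 2)), tx)
  ev <- data.frame(mirna_id = "m", transcript_id = "t1",
                   cleavage_position = 100L, peak_count = 1L, category = 4L,
                   site_start = 89L, site_end = 109L, stringsAsFactors = FALSE)
  td <- tplot_data("t1", d, ev)
  expect_identical(which(td$is_cleavage_site), 100L)
  expect_identical(td$count[100], d$t1[100])
  expect_error(tplot_data("nope", d, ev), "unknown transcript")
})

test_that("zero-background simulation recovers every planted cleavage exactly", {
  mirs <- c(mirA = random_dna(1, 21, seed = 46), mirB = random_dna(1, 21, seed = 47))
  tx <- simulate_transcriptome_with_targets(mirs, seed = 48)
  dg <- simulate_degradome(tx$transcripts, tx$truth, background_rate = 0, seed = 48)
  d <- build_density(dg$reads, tx$transcripts)
  targets <- scan_transcriptome(mirs, tx$transcripts)
  ev <- detect_cleavage(targets, d)
  got <- paste(ev$transcript_id, ev$cleavage_position)
  want <- paste(dg$truth$transcript_id, dg$truth$cleavage_position)
  expect_setequal(got, want)
  # peak counts equal the planted counts when background is zero
  m <- match(got, want)
  expect_identical(ev$peak_count, dg$truth$expected_peak_count[m])
})
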