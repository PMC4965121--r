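# Read cleaning, accounting identity, tag collapsing and composition.

test_that("filter_summary reproduces the published accounting identity", {
  s <- filter_summary(17186803, 17103178, 6753, 3712, 31246, 386179, 115)
  expect_identical(s$clean_reads, 16675173L)
  expect_equal(s$percentages[["clean_reads"]], 97.50)
  expect_equal(s$percentages[["high_quality"]], 100.00)
  expect_error(filter_summary(10, 20, 0, 0, 0, 0, 0), "inconsistent")
  expect_error(filter_summary(30, 20, 21, 0, 0, 0, 0), "exceed")
})

test_that("the cleaning cascade assigns each read to exactly one category", {
  a3 <- DEFAULT_ADAPTER3; a5 <- DEFAULT_ADAPTER5
  mk <- function(seq, q = strrep("I", nchar(seq))) c(seq, q)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:7),
    sequence = c(
      paste0(strrep("C", 21), a3),                         # clean
      strrep("G", 40),                                     # no 3' adapter
      a3,                                                  # insert null
      paste0(substr(a5, nchar(a5) - 7, nchar(a5)), strrep("C", 20), a3),  # 5' contaminant
      paste0(strrep("G", 10), a3),                         # shorter than 18
      paste0(strrep("A", 25), a3),                         # poly(A)
      paste0(strrep("C", 21), a3)),                        # low quality
    stringsAsFactors = FALSE)
  reads$quality <- strrep("I", nchar(reads$sequence))
  reads$quality[7] <- strrep("#", nchar(reads$sequence[7]))
  fl <- filter_reads(reads, a3, a5)
  expect_identical(fl$category,
                   c("clean", "adaptor3_null", "insert_null",
                     "adaptor5_contaminant", "shorter_than_18", "polyA",
                     "low_quality"))
  expect_identical(fl$summary$clean_reads, 1L)
  expect_identical(fl$clean$sequence, strrep("C", 21))
  # partition: category counts sum to the high-quality total
  expect_equal(
    sum(vapply(c("adaptor3_null", "insert_null", "adaptor5_contaminant",
                 "shorter_than_18", "polyA"),
               function(k) fl$summary[[k]], integer(1))) + fl$summary$clean_reads,
    fl$summary$high_quality)
})

test_that("accounting identity holds on fuzzed random read sets", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(50:150, 1)
    seqs <- vapply(seq_len(n), function(i) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(c(5, 15, 21, 25), 1),
                          replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                   collapse = "")
      if (runif(1) < 0.8) paste0(ins, DEFAULT_ADAPTER3) else ins
    }, character(1))
    reads <- data.frame(read_id = sprintf("r%d", seq_len(n)), sequence = seqs,
                        quality = strrep(sample(c("I", "#"), n, TRUE,
                                                prob = c(.9, .1)), nchar(seqs)),
                        stringsAsFactors = FALSE)
    fl <- filter_reads(reads)
    cats <- table(fl$category)
    expect_identical(sum(cats), as.integer(n))
    expect_equal(
      fl$summary$high_quality - sum(vapply(
        c("adaptor3_null", "insert_null", "adaptor5_contaminant",
          "shorter_than_18", "polyA"), function(k) fl$summary[[k]], integer(1))),
      fl$summary$clean_reads)
  }
})

test_that("collapse_tags collapses duplicates and conserves counts", {
  s <- random_dna(1, 21, seed = 11)
  tags <- collapse_tags(rep(s, 5))
  expect_identical(nrow(tags), 1L)
  expect_identical(tags$count, 5L)
  expect_identical(tags$sequence, s)
  expect_identical(nrow(collapse_tags(character(0))), 0L)
  mix <- c(rep(random_dna(1, 19, seed = 1), 3), rep(random_dna(1, 24, seed = 2), 7))
  expect_identical(sum(collapse_tags(mix)$count), length(mix))
  # out-of-window lengths are dropped
  expect_identical(nrow(collapse_tags(c("ACGT", strrep("A", 35)))), 0L)
})

test_that("composition stats count first nucleotides and normalise positions", {
  tag <- paste0("T", random_dna(1, 20, seed = 3))
  tags <- data.frame(tag_id = "t1", sequence = tag, count = 7L)
  cs <- composition_stats(tags)
  expect_identical(cs$first_nt_by_length$redundant["21", "U"], 7L)
  expect_identical(cs$first_nt_by_length$unique["21", "U"], 1L)
  expect_identical(cs$length_counts$redundant, 7L)
  expect_true(all(abs(rowSums(cs$positional_nt_fraction) - 1) < 1e-12))
})

test_that("a simulated library reproduces its truth-sidecar class counts", {
  lib <- fixture_library()
  fl <- filter_reads(lib$reads)
  ttab <- table(lib$truth$class)
  for (k in c("adaptor3_null", "insert_null", "adaptor5_contaminant",
              "shorter_than_18", "polyA")) {
    want <- if (k %in% names(ttab)) as.integer(ttab[[k]]) else 0L
    expect_identical(as.integer(fl$summary[[k]]), want, info = k)
  }
  expect_identical(as.integer(fl$summary$total_reads - fl$summary$high_quality),
                   as.integer(ttab[["low_quality"]]))
  tags <- collapse_tags(fl$clean)
  expect_identical(sum(tags$count), as.integer(fl$summary$clean_reads))
  # 5'-U bias of planted mature reads follows the spec fraction
  spec <- fixture_spec()
  mat <- lib$truth$insert[lib$truth$class == "novel_mature"]
  u_frac <- mean(substr(mat, 1, 1) == "T")
  p <- spec$first_nt_u_bias
  # planted matures start with U at the bias rate (binomial 3 SD over hairpins)
  expect_lt(abs(u_frac - p), 3 * sqrt(p * (1 - p) / length(unique(mat))) + 0.05)
})
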