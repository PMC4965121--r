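# Hairpin duplex metrics and the nine-criterion evaluation.

test_that("duplex metrics of hand-built structures", {
  # perfect 21-bp duplex: flank(5) mature(21) loop(6) star(21) flank(5)
  st <- paste0(strrep(".", 5), strrep("(", 21), strrep(".", 6),
               strrep(")", 21), strrep(".", 5))
  m <- duplex_metrics(st, 6, 26)
  expect_identical(m$paired_bases, 21L)
  expect_identical(m$max_bulge, 0L)
  expect_identical(m$asymmetry, 0L)
  expect_identical(m$loop_space, 6L)
  expect_identical(c(m$flank5, m$flank3), c(5L, 5L))
  # star coordinates carry the 2-nt 3' overhang
  expect_identical(c(m$star_start, m$star_end), c(33L + 2L, 53L + 2L))

  # one 2-nt bulge on the mature side: 10 paired, 2 bulged, 9 paired vs 19 star
  st2 <- paste0(strrep(".", 5), strrep("(", 10), "..", strrep("(", 9),
                strrep(".", 6), strrep(")", 19), strrep(".", 5))
  m2 <- duplex_metrics(st2, 6, 26)
  expect_identical(m2$paired_bases, 19L)
  expect_identical(m2$max_bulge, 2L)
  expect_identical(m2$asymmetry, 2L)

  # mature pairing nothing outside itself -> duplex undefined
  expect_null(duplex_metrics(strrep(".", 40), 6, 26))
})

test_that("each criterion is judged independently at its boundary", {
  cand <- list(mfe = -30, mature_start = 21, mature_end = 41)
  m <- list(paired_bases = 21L, max_bulge = 0L, asymmetry = 0L,
            loop_space = 10L, star_start = 54L, star_end = 74L,
            flank5 = 20L, flank3 = 20L)
  base <- apply_novel_criteria(cand, m)
  expect_true(base$overall)

  fail_only <- function(ev, name) {
    got <- setNames(ev$report$pass, ev$report$criterion)
    expect_false(got[[name]])
    expect_true(all(got[setdiff(names(got), name)]))
  }
  m2 <- m; m2$paired_bases <- 15L
  fail_only(apply_novel_criteria(cand, m2), "min_paired")
  expect_true(apply_novel_criteria(cand, within(m, paired_bases <- 16L))$overall)

  c2 <- cand; c2$mfe <- -17.5
  fail_only(apply_novel_criteria(c2, m), "mfe")
  c3 <- cand; c3$mfe <- -18.32
  expect_true(apply_novel_criteria(c3, m)$overall)

  c4 <- cand; c4$mature_end <- 46     # 26-nt mature breaks both length windows
  ev <- apply_novel_criteria(c4, m)
  got <- setNames(ev$report$pass, ev$report$criterion)
  expect_false(got[["mature_len"]])
  expect_false(got[["ref_len"]])

  fail_only(apply_novel_criteria(cand, within(m, max_bulge <- 5L)), "max_bulge")
  fail_only(apply_novel_criteria(cand, within(m, asymmetry <- 5L)), "max_asymmetry")
  fail_only(apply_novel_criteria(cand, within(m, loop_space <- 301L)), "loop_space")
  fail_only(apply_novel_criteria(cand, within(m, flank5 <- 10L)), "flank")
  fail_only(apply_novel_criteria(cand, m, n_genome_copies = 21L), "max_ref_copies")
})

test_that("excision ignores loci without read support or without hits", {
  planted <- fixture_planted()
  expect_identical(excise_candidates(planted$genome,
                                     data.frame(tag_id = character(),
                                                tag_sequence = character(),
                                                scaffold = character(),
                                                start = integer(), end = integer(),
                                                strand = character(),
                                                mismatches = integer()),
                                     data.frame(tag_id = character(),
                                                sequence = character(),
                                                count = integer())),
                   list())
  # a tag below the support floor yields no candidate
  truth <- planted$truth[1, ]
  tags <- data.frame(tag_id = "t1", sequence = truth$mature_seq, count = 2L)
  hits <- map_tags(tags, planted$genome)
  expect_identical(length(excise_candidates(planted$genome, hits, tags)), 0L)
})

test_that("emitted novel miRNAs re-pass the criteria when re-folded from scratch", {
  pred <- fixture_prediction()$result
  expect_gt(nrow(pred$novel), 0L)
  for (i in seq_len(nrow(pred$novel))) {
    row <- pred$novel[i, ]
    fr <- fold_rna(row$precursor)
    expect_identical(fr$structure, row$structure)
    expect_equal(fr$mfe, row$mfe)
    m <- duplex_metrics(fr$structure, row$mature_start, row$mature_end)
    ev <- apply_novel_criteria(list(mfe = fr$mfe, mature_start = row$mature_start,
                                    mature_end = row$mature_end), m)
    expect_true(ev$overall, info = row$id)
    expect_true(row$precursor_length >= 50 && row$precursor_length <= 400)
  }
  # ids are zero-padded and assigned in genome order
  expect_identical(pred$novel$id, sprintf("m%04d", seq_len(nrow(pred$novel))))
  ord <- order(pred$novel$scaffold, pred$novel$start)
  expect_identical(ord, seq_len(nrow(pred$novel)))
})
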