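# Genome mapping and the annotation-category cascade.

test_that("map_tags reports planted coordinates on both strands", {
  set.seed(21)
  g <- random_dna(1, 3000)
  tag <- random_dna(1, 21)
  g <- paste0(substr(g, 1, 1000), tag, substr(g, 1022, 3000))
  genome <- c(scaffold1 = g)
  tags <- data.frame(tag_id = c("t1", "t2", "t3"),
                     sequence = c(tag, revcomp(tag), random_dna(1, 21)),
                     count = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  hits <- map_tags(tags, genome)
  h1 <- hits[hits$tag_id == "t1", ]
  expect_identical(unname(unlist(h1[, c("scaffold", "start", "end", "strand")])),
                   c("scaffold1", "1001", "1021", "+"))
  # reverse complement maps to the minus strand at the same locus
  h2 <- hits[hits$tag_id == "t2", ]
  expect_identical(c(h2$start, h2$end, h2$strand), c(1001L, 1021L, "-"))
  expect_false("t3" %in% hits$tag_id)   # absent tag: no hits
  expect_error(map_tags(tags, character(0)), "empty genome")
})

test_that("classification follows the precedence order and strandedness", {
  g <- random_dna(1, 2000, seed = 22)
  rRNA_seq <- substr(g, 101, 400)
  exon_seq <- substr(g, 901, 1200)
  ann <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(c(101, 301, 901), c(400, 600, 1200)),
    strand = c("+", "+", "-"))
  ann$type <- c("rRNA", "intron", "exon")
  genome <- c(s1 = g)
  tags <- data.frame(
    tag_id = c("t1", "t2", "t3"),
    sequence = c(substr(g, 380, 401),      # overlaps rRNA AND intron
                 substr(g, 1000, 1020),    # sense of a minus-strand exon?
                 revcomp(substr(g, 1000, 1020))),
    count = c(5L, 2L, 4L), stringsAsFactors = FALSE)
  hits <- map_tags(tags, genome)
  cls <- classify_tags(tags, hits, ann)
  cat <- setNames(cls$category$category, cls$category$tag_id)
  expect_identical(cat[["t1"]], "rRNA")          # precedence over intron
  # t2 maps + strand over a minus-strand exon -> antisense; t3 is its
  # reverse complement and maps the minus strand -> sense
  expect_identical(cat[["t2"]], "exon_antisense")
  expect_identical(cat[["t3"]], "exon_sense")
  # partition invariants
  smry <- cls$summary
  tot <- smry[smry$category == "Total", ]
  expect_identical(tot$unique_count, nrow(tags))
  expect_identical(tot$redundant_count, sum(tags$count))
})

test_that("known-miRNA sequences outrank everything and tolerate 1 mismatch", {
  g <- random_dna(1, 1000, seed = 23)
  mir <- substr(g, 201, 221)  # also lies inside an rRNA feature
  ann <- GenomicRanges::GRanges("s1", IRanges::IRanges(150, 400), strand = "+")
  ann$type <- "rRNA"
  variant <- paste0("A", substr(mir, 2, 21))
  tags <- data.frame(tag_id = c("t1", "t2"), sequence = c(mir, variant),
                     count = c(2L, 1L), stringsAsFactors = FALSE)
  hits <- map_tags(tags, c(s1 = g))
  cls <- classify_tags(tags, hits, ann, known_mirnas = mir)
  expect_identical(cls$category$category, c("miRNA", "miRNA"))
})

test_that("classification is invariant to tag input order", {
  lib <- fixture_library()
  planted <- fixture_planted()
  fl <- filter_reads(lib$reads)
  tags <- collapse_tags(fl$clean)
  tags <- tags[tags$count >= 3, ][1:50, ]  # small stable subset
  hits <- map_tags(tags, planted$genome)
  c1 <- classify_tags(tags, hits, planted$annotation)
  perm <- rev(seq_len(nrow(tags)))
  c2 <- classify_tags(tags[perm, ], hits, planted$annotation)
  m1 <- setNames(c1$category$category, c1$category$tag_id)
  m2 <- setNames(c2$category$category, c2$category$tag_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("category_summary reproduces the published percentage columns", {
  t3 <- published_counts("table3_category_counts")
  smry <- category_summary(setNames(t3$unique_count, t3$category),
                           setNames(t3$redundant_count, t3$category))
  printed_unique <- c(2.45, 4.40, 2.33, 3.52, 1.18, 2.56, 0.08, 0.03, 0.30, 83.14)
  printed_redundant <- c(1.50, 3.09, 1.58, 3.43, 21.92, 14.05, 0.07, 0.02, 4.42, 49.91)
  got <- smry[smry$category != "Total", ]
  expect_equal(got$unique_pct, printed_unique)
  expect_equal(got$redundant_pct, printed_redundant)
  tot <- smry[smry$category == "Total", ]
  expect_identical(tot$unique_count, 3328500L)
  expect_identical(tot$redundant_count, 16675173L)
})

test_that("a synthetic library classifies to its truth classes", {
  lib <- fixture_library()
  planted <- fixture_planted()
  db <- simulate_known_db(seed = 101L)
  fl <- filter_reads(lib$reads)
  tags <- collapse_tags(fl$clean)
  hits <- map_tags(tags, planted$genome)
  cls <- classify_tags(tags, hits, planted$annotation, known_mirnas = db)
  tag_cat <- setNames(cls$category$category, cls$category$tag_id)
  tag_of <- setNames(tags$tag_id, tags$sequence)
  clean_classes <- c(miRNA = "miRNA", rRNA = "rRNA", tRNA = "tRNA",
                     snRNA = "snRNA", snoRNA = "snoRNA",
                     exon_sense = "exon_sense", exon_antisense = "exon_antisense",
                     intron_sense = "intron_sense",
                     intron_antisense = "intron_antisense", "repeat" = "repeat",
                     novel_mature = "unannotated", novel_star = "unannotated",
                     unannotated = "unannotated")
  truth <- lib$truth[lib$truth$class %in% names(clean_classes), ]
  got <- tag_cat[tag_of[truth$insert]]
  expect_identical(unname(got), unname(clean_classes[truth$class]))
})
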