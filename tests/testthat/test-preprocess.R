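test_that("width normalization maps all full-width code points, idempotently", {
  expect_equal(normalizeWidth(""), "")
  expect_equal(normalizeWidth("abc 12"), "abc 12")
  mixed <- "ａｂｃ１２３ x　y"
  out <- normalizeWidth(mixed)
  expect_equal(out, "abc123 x y")
  expect_equal(nchar(out), nchar(mixed))  # 1:1 mapping preserves offsets
  expect_equal(normalizeWidth(out), out)
  # derived check: random strings with k full-width characters come back the
  # same length with zero full-width code points remaining
  set.seed(4)
  for (r in 1:20) {
    asc <- paste(sample(c(letters, 0:9, "-", "_"), 12, TRUE), collapse = "")
    k <- sample(1:12, 1)
    cp <- utf8ToInt(asc)
    pos <- sample(12, k)
    cp[pos] <- cp[pos] + 0xFEE0L
    s <- intToUtf8(cp)
    expect_true(tcmdx:::hasFullWidth(s))
    o <- normalizeWidth(s)
    expect_equal(nchar(o), nchar(s))
    expect_false(tcmdx:::hasFullWidth(o))
    expect_equal(o, asc)
  }
})

test_that("non-text placeholders are removed and spans re-aligned", {
  note <- structure(list(
    note_id = "n1",
    sections = list(present_illness = "sym_a <img> 3-days <img> sym_b"),
    spans = data.frame(section = "present_illness",
                       start = c(0L, 12L, 25L), end = c(5L, 18L, 30L),
                       type = c("symptom", "duration", "symptom"),
                       canonical = c("sym_a", "3-days", "sym_b"),
                       stringsAsFactors = FALSE),
    disease = "D01", syndrome = "S01", qc_flags = character(0)),
    class = "tcmNote")
  out <- stripNontext(note)
  expect_equal(out$sections$present_illness, "sym_a 3-days sym_b")
  expect_equal(out$spans$start, c(0L, 6L, 13L))
  expect_equal(out$spans$end, c(5L, 12L, 18L))
  # no placeholders: identical note
  clean <- note
  clean$sections$present_illness <- "sym_a 3-days sym_b"
  clean$spans <- out$spans
  expect_identical(stripNontext(clean), clean)
  # only placeholders: empty section
  only <- note
  only$sections$present_illness <- "<img> <table>"
  only$spans <- only$spans[0, ]
  expect_equal(stripNontext(only)$sections$present_illness, "")
})

test_that("section splitting assigns every character and handles edge cases", {
  notes <- smallCorpus(n = 3, seed = 2, fullWidthProb = 0)
  raw <- renderNote(notes[[1]])
  sec <- splitSections(raw)
  expect_equal(sec[names(notes[[1]]$sections)], notes[[1]]$sections)

  expect_equal(splitSections("free text only"), list(preamble = "free text only"))
  dup <- "[tongue]\na\n[tongue]\nb"
  expect_message(out <- splitSections(dup), "duplicated")
  expect_equal(out$tongue, "a\nb")
})

test_that("QC filter discards exactly the planted violations with reasons", {
  ont <- smallOntology()
  counts <- stats::setNames(rep(10, 3), ont$diseases)
  clean <- quietly(generateCorpus(genConfig(ont, counts, seed = 3)))
  rep0 <- qcFilter(clean)
  expect_length(rep0$kept, 30)
  expect_equal(nrow(rep0$discarded), 0)

  notes <- quietly(generateCorpus(genConfig(
    ont, counts, seed = 3,
    qcViolations = c(missing_page = 2, inconsistent = 2,
                     nonstandard_complaint = 2))))
  rep1 <- qcFilter(notes)
  expect_length(rep1$kept, 24)
  expect_equal(sort(unname(table(rep1$discarded$reason))), c(2L, 2L, 2L),
               ignore_attr = TRUE)
  expect_equal(as.vector(table(rep1$discarded$reason)[c("incomplete")]), 2L)
  # partition property: kept and discarded cover the input disjointly
  ids <- vapply(notes, `[[`, "", "note_id")
  expect_setequal(c(rep1$kept, rep1$discarded$note_id), ids)
  expect_length(intersect(rep1$kept, rep1$discarded$note_id), 0)
  flagged <- vapply(notes, function(n) length(n$qc_flags) > 0, NA)
  expect_setequal(rep1$discarded$note_id, ids[flagged])
})

test_that("a corpus with the published violation count keeps 22,984 notes", {
  ont <- buildOntology(4, 8, 2, seed = 1)
  counts <- c(D01 = 6000, D02 = 6000, D03 = 6000, D04 = 5719)  # 23,719 total
  notes <- quietly(generateCorpus(genConfig(
    ont, counts, seed = 5, synonymProb = 0, fullWidthProb = 0,
    qcViolations = c(missing_page = 245, inconsistent = 245,
                     nonstandard_complaint = 245))))  # 735 planted
  expect_length(notes, 23719)
  rep <- qcFilter(notes)
  expect_equal(nrow(rep$discarded), 735)
  expect_length(rep$kept, 22984)
})

test_that("class balancing hits the target exactly, by both directions", {
  set.seed(11)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("a", "b"), c(20, 10))
  out <- balanceClasses(x, y, 15, seed = 1)
  expect_equal(as.vector(table(out$labels)), c(15L, 15L))
  # downsampled class consists of original rows only
  keyIn <- apply(x[y == "a", ], 1, paste, collapse = ",")
  keyOut <- apply(out$x[out$labels == "a", ], 1, paste, collapse = ",")
  expect_true(all(keyOut %in% keyIn))
  expect_false(anyDuplicated(keyOut) > 0)
  # upsampled class: originals present, interpolants inside the class box
  xb <- out$x[out$labels == "b", ]
  expect_true(all(apply(x[y == "b", ], 1, paste, collapse = ",") %in%
                    apply(xb, 1, paste, collapse = ",")))
  lo <- apply(x[y == "b", ], 2, min); hi <- apply(x[y == "b", ], 2, max)
  expect_true(all(t(xb) >= lo - 1e-12 & t(xb) <= hi + 1e-12))
  # already at target: a permutation of the input
  same <- balanceClasses(x, y, 20, seed = 2)
  expect_equal(as.vector(table(same$labels)), c(20L, 20L))
  # deterministic
  expect_identical(balanceClasses(x, y, 15, seed = 3),
                   balanceClasses(x, y, 15, seed = 3))
})

test_that("the published rebalancing sizes (109 -> 1000, 2180 -> 1000) hold", {
  set.seed(12)
  x <- rbind(matrix(rnorm(2180 * 3, 0), 2180, 3),
             matrix(rnorm(109 * 3, 5), 109, 3))
  y <- rep(c("cluster", "asthma"), c(2180, 109))
  out <- balanceClasses(x, y, 1000, seed = 9)
  expect_equal(sum(out$labels == "asthma"), 1000)
  expect_equal(sum(out$labels == "cluster"), 1000)
  # downsampled majority rows all existed in the input
  keyIn <- apply(x[y == "cluster", ], 1, paste, collapse = ",")
  keyOut <- apply(out$x[out$labels == "cluster", ], 1, paste, collapse = ",")
  expect_true(all(keyOut %in% keyIn))
})

test_that("balancing a singleton class below target errors", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(balanceClasses(x, c("a", "a", "a", "a", "b"), 3, seed = 1),
               "interpolation")
})

test_that("partitioning gives floor(N/10) validation and test sets", {
  p <- partitionCorpus(as.character(1:10), seed = 1)
  expect_equal(lengths(p[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  # the published corpus size yields the published validation count
  ids <- sprintf("n%05d", 1:22984)
  p2 <- partitionCorpus(ids, seed = 2)
  expect_length(p2$val, 2298)
  expect_length(p2$test, 2298)
  expect_length(p2$train, 22984 - 2 * 2298)
  expect_setequal(c(p2$train, p2$val, p2$test), ids)
  expect_identical(partitionCorpus(ids, seed = 2), p2)
  expect_error(partitionCorpus(character(0)), "empty")
  expect_error(partitionCorpus(c("a", "a")), "unique")
})

test_that("stratified partitioning spreads classes as evenly as floors allow", {
  set.seed(3)
  ids <- sprintf("x%04d", 1:200)
  strata <- rep(c("A", "B", "C", "D"), c(100, 60, 30, 10))
  p <- partitionCorpus(ids, strata = strata, seed = 4)
  sv <- table(strata[match(p$val, ids)])
  expect_equal(sum(sv), 20)
  expect_true(all(abs(sv - c(10, 6, 3, 1)) <= 1))
})
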