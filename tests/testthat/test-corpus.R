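test_that("per-class note counts are honored exactly", {
  ont <- buildOntology(2, 3, 2, seed = 1)
  notes <- quietly(generateCorpus(genConfig(ont, c(D01 = 5, D02 = 7), seed = 3)))
  expect_length(notes, 12)
  dis <- vapply(notes, `[[`, "", "disease")
  expect_equal(unname(table(dis)[c("D01", "D02")]), c(5L, 7L),
               ignore_attr = TRUE)
})

test_that("the published class imbalance profile is reproduced exactly", {
  # cluster disease / diabetes / asthma / spleen disease note counts
  ont <- buildOntology(4, 8, 2, seed = 1)
  counts <- c(D01 = 2180, D02 = 1913, D03 = 109, D04 = 584)
  notes <- quietly(generateCorpus(genConfig(ont, counts, seed = 2,
                                            synonymProb = 0, fullWidthProb = 0)))
  dis <- vapply(notes, `[[`, "", "disease")
  expect_equal(as.vector(table(dis)[names(counts)]), unname(counts))
})

test_that("corpus generation is byte-reproducible for a fixed config", {
  ont <- smallOntology()
  cfg <- genConfig(ont, stats::setNames(rep(4, 3), ont$diseases),
                   qcViolations = c(missing_page = 1), seed = 7)
  a <- quietly(generateCorpus(cfg))
  b <- quietly(generateCorpus(cfg))
  expect_identical(a, b)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  writeCorpus(a, fa); writeCorpus(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("gold spans index their section text correctly", {
  notes <- smallCorpus(n = 10)
  for (note in notes) {
    sp <- note$spans
    for (i in seq_len(nrow(sp))) {
      txt <- normalizeWidth(note$sections[[sp$section[i]]])
      expect_lte(sp$end[i], nchar(txt))
      surf <- substring(txt, sp$start[i] + 1L, sp$end[i])
      # surface is the canonical term or one of its synonym variants
      expect_equal(sub("~[a-z]$", "", surf), sp$canonical[i])
    }
    # spans within a section are non-overlapping
    for (nm in unique(sp$section)) {
      s <- sp[sp$section == nm, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
  }
})

test_that("syndrome labels respect the ontology map", {
  ont <- smallOntology()
  notes <- smallCorpus(n = 15, ont = ont)
  for (note in notes) {
    expect_true(note$syndrome %in% ont$map[[note$disease]])
  }
})

test_that("QC violations are planted in exactly the configured counts", {
  ont <- smallOntology()
  counts <- stats::setNames(rep(10, 3), ont$diseases)
  notes <- quietly(generateCorpus(genConfig(
    ont, counts, seed = 4,
    qcViolations = c(missing_page = 2, inconsistent = 3,
                     nonstandard_complaint = 1))))
  flags <- unlist(lapply(notes, `[[`, "qc_flags"))
  expect_equal(sum(flags == "missing_page"), 2)
  expect_equal(sum(flags == "inconsistent"), 3)
  expect_equal(sum(flags == "nonstandard_complaint"), 1)
  missing <- Filter(function(n) "missing_page" %in% n$qc_flags, notes)
  expect_true(all(vapply(missing, function(n) is.null(n$sections$discharge), NA)))
})

test_that("violation counts beyond the corpus size are rejected", {
  ont <- buildOntology(1, 1, 1, seed = 1)
  expect_error(genConfig(ont, c(D01 = 2), qcViolations = c(missing_page = 3)),
               "exceed")
  expect_error(genConfig(ont, c(D01 = -1)), ">= 0")
})

test_that("zero synonym noise keeps disease symptom lexica disjoint", {
  ont <- buildOntology(3, 4, 1, seed = 6)
  notes <- smallCorpus(n = 20, ont = ont, noiseProb = 0)
  dis <- vapply(notes, `[[`, "", "disease")
  dsyms <- lapply(split(notes, dis), function(ns) {
    sp <- do.call(rbind, lapply(ns, `[[`, "spans"))
    unique(grep("^sym_D", sp$canonical, value = TRUE))
  })
  for (i in seq_along(dsyms)) {
    for (j in seq_along(dsyms)) {
      if (i < j) expect_length(intersect(dsyms[[i]], dsyms[[j]]), 0)
    }
  }
})

test_that("JSONL corpus round-trips to identity", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeCorpus(list(), f)
  expect_identical(readCorpus(f), list())

  notes <- smallCorpus(n = 3, seed = 8)
  writeCorpus(notes, f)
  expect_identical(readCorpus(f), notes)
  expect_length(readLines(f), length(notes))
})

test_that("CoNLL BIO export follows the tagging contract", {
  notes <- smallCorpus(n = 2, seed = 9, synonymProb = 0, fullWidthProb = 0)
  f <- withr::local_tempfile(fileext = ".conll")
  writeConll(notes, f)
  blocks <- readConll(f)
  expect_equal(length(blocks),
               sum(vapply(notes, function(n) length(n$sections), 0L)))
  # chief complaint block: symptom duration symptom duration pattern
  b1 <- blocks[[1]]
  expect_equal(b1$section, "chief_complaint")
  expect_equal(b1$tags, c("B-symptom", "B-duration", "B-symptom", "B-duration"))
  # multi-token span encodes as B- then I-
  tok <- tokenizeWithOffsets("a b c")
  sp <- data.frame(section = "s", start = 0L, end = 3L, type = "symptom")
  expect_equal(tcmdx:::bioTags(tok, sp), c("B-symptom", "I-symptom", "O"))
})

test_that("malformed CoNLL lines report the line number", {
  f <- withr::local_tempfile()
  writeLines(c("# note=a section=b", "tok1\tB-symptom", "bad line no tab"), f)
  expect_error(readConll(f), "line 3")
})
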