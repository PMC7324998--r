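test_that("BIO decoding follows the span and repair rules", {
  expect_equal(decodeEntities(c("B-symptom", "I-symptom", "O")),
               data.frame(start = 0L, end = 2L, type = "symptom",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(decodeEntities(rep("O", 5))), 0)
  # orphan I- is repaired to a span start
  expect_equal(decodeEntities(c("I-symptom", "O", "B-symptom")),
               data.frame(start = c(0L, 2L), end = c(1L, 3L),
                          type = c("symptom", "symptom"), stringsAsFactors = FALSE))
  # type change inside a run starts a new span
  expect_equal(decodeEntities(c("B-symptom", "I-pulse"))$start, c(0L, 1L))
  expect_error(decodeEntities(c("B-symptom", "X-huh")), "unknown tag")
})

test_that("tag encoding then decoding is the identity on legal span sets", {
  set.seed(31)
  types <- tcmEntityTypes()
  for (r in 1:25) {
    n <- sample(3:12, 1)
    tags <- rep("O", n)
    # plant random non-overlapping spans
    spans <- data.frame(start = integer(0), end = integer(0), type = character(0))
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < 0.5) {
        len <- sample(1:min(3, n - i + 1L), 1)
        ty <- sample(types, 1)
        tags[i:(i + len - 1L)] <- c(paste0("B-", ty),
                                    rep(paste0("I-", ty), len - 1L))
        spans <- rbind(spans, data.frame(start = i - 1L, end = i + len - 1L,
                                         type = ty))
        i <- i + len
      }
      i <- i + 1L
    }
    got <- decodeEntities(tags)
    rownames(spans) <- NULL
    expect_equal(got, spans[, c("start", "end", "type")])
  }
})

test_that("the tag scheme is a total bijection of size 2*types + 1", {
  sch <- tagScheme(c("a", "b"))
  expect_length(sch$tags, 5)
  expect_equal(unname(sch$index[sch$tags]), 1:5)
  expect_equal(sch$start, 6L)
  expect_equal(sch$stop, 7L)
})

test_that("durations attach to the nearest preceding symptom in-section", {
  # analog of the worked chief complaint: two dated symptoms yield two pairs
  note <- structure(list(
    note_id = "w1",
    sections = list(chief_complaint = "coughing 3-days coughing_phlegm 2-days"),
    spans = data.frame(
      section = "chief_complaint", start = c(0L, 9L, 16L, 32L),
      end = c(8L, 15L, 31L, 38L),
      type = c("symptom", "duration", "symptom", "duration"),
      canonical = c("coughing", "3-days", "coughing_phlegm", "2-days"),
      stringsAsFactors = FALSE),
    disease = "D", syndrome = "S", qc_flags = character(0)), class = "tcmNote")
  rec <- structureRecord(note)
  expect_equal(rec$canonical, c("coughing", "coughing_phlegm"))
  expect_equal(rec$duration, c("3-days", "2-days"))
  expect_equal(rec$durationDays, c(3, 2))

  # no durations: symptoms stay unpaired
  und <- note
  und$spans <- und$spans[c(1, 3), ]
  expect_true(all(is.na(structureRecord(und)$duration)))

  # a duration before any symptom is unpaired and logged
  orphan <- note
  orphan$spans <- orphan$spans[c(2, 3), ]
  expect_message(rec2 <- structureRecord(orphan), "unpaired")
  expect_true(is.na(rec2$duration))
})

test_that("duration parsing applies the day/month/year unit table", {
  expect_equal(parseDuration(c("3-days", "2-months", "1-years", "junk")),
               c(3, 60, 365, NA))
})

test_that("an untrained model (0 epochs) returns its initialization", {
  notes <- smallCorpus(n = 4, seed = 41)
  m0 <- nerFit(notes, notes, nerConfig(epochs = 0, seed = 7))
  init <- tcmdx:::initNerParams(length(m0$vocab), m0$config$embedDim,
                                m0$config$hiddenDim, m0$scheme$K, 7)
  expect_identical(m0$params, init)
  expect_length(m0$valF1Trace, 0)
})

test_that("training on a separable corpus reaches high span F1, reproducibly", {
  ont <- smallOntology()
  notes <- smallCorpus(n = 17, seed = 42, ont = ont, noiseProb = 0)
  train <- notes[1:40]; val <- notes[41:51]
  cfg <- nerConfig(epochs = 5, seed = 3)
  m <- quietly(nerFit(train, val, cfg))
  ev <- quietly(nerEvaluate(m, val))
  expect_gte(ev$f1, 0.95)
  # training loss decreases over early epochs on the fixture
  expect_true(max(m$valF1Trace) >= m$valF1Trace[1])
  # same seed twice: identical validation trace
  m2 <- quietly(nerFit(train, val, cfg))
  expect_identical(m$valF1Trace, m2$valF1Trace)
  expect_identical(m$params, m2$params)
})

test_that("empty training input errors", {
  expect_error(nerFit(list()), "empty")
})
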