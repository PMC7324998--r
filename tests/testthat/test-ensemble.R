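test_that("majority vote follows the stated examples", {
  expect_equal(majorityVote(c("A", "A", "A", "B"), c(0.5, 0.5, 0.5, 0.99)), "A")
  # 2-2 tie: higher mean confidence wins
  expect_equal(majorityVote(c("A", "A", "B", "B"), c(0.9, 0.9, 0.6, 0.6)), "A")
  # 1-1-1-1 tie: the most confident single voter wins
  expect_equal(majorityVote(c("A", "B", "C", "D"), c(0.5, 0.7, 0.6, 0.4)), "B")
  # residual tie (equal confidence): lexicographic order
  expect_equal(majorityVote(c("B", "A", "C", "D"), rep(0.5, 4)), "A")
})

test_that("three or more agreeing voters always win regardless of confidence", {
  set.seed(61)
  labels <- c("x", "y", "z", "w")
  for (r in 1:50) {
    maj <- sample(labels, 1)
    other <- sample(setdiff(labels, maj), 1)
    votes <- c(rep(maj, 3), other)[sample.int(4)]
    expect_equal(majorityVote(votes, stats::runif(4)), maj)
  }
})

test_that("a single-syndrome disease yields a constant predictor", {
  x <- matrix(rnorm(20), 10, 2)
  expect_message(m <- fitIntegrated("D01", x, rep("S01", 10), seed = 1),
                 "single syndrome")
  expect_true(m$degenerate)
  reg <- structure(list(models = list(D01 = m), diseases = "D01"),
                   class = "tcmRegistry")
  p <- predictSyndrome(x[1, ], "D01", reg)
  expect_equal(p$syndrome, "S01")
  expect_equal(nrow(p), 1)
})

test_that("fitting requires two records per represented syndrome", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fitIntegrated("D", x, c("a", "a", "a", "a", "b"), seed = 1),
               "< 2 records")
})

test_that("integrated models fit, predict and serialize deterministically", {
  set.seed(62)
  n <- 60
  y <- sample(c("S1", "S2", "S3"), n, TRUE)
  x <- matrix(rnorm(n * 4), n, 4) +
    3 * outer(match(y, c("S1", "S2", "S3")), rep(1, 4))
  colnames(x) <- paste0("f", 1:4)
  m1 <- quietly(fitIntegrated("D01", x, y, seed = 5))
  m2 <- quietly(fitIntegrated("D01", x, y, seed = 5))
  expect_length(m1$learners, 4)
  expect_named(m1$learners, c("bp", "svc", "rf", "xgb"))
  reg1 <- structure(list(models = list(D01 = m1), diseases = "D01"),
                    class = "tcmRegistry")
  reg2 <- structure(list(models = list(D01 = m2), diseases = "D01"),
                    class = "tcmRegistry")
  probe <- x[sample(n, 10), , drop = FALSE]
  p1 <- apply(probe, 1, function(r) predictSyndrome(r, "D01", reg1)$syndrome[1])
  p2 <- apply(probe, 1, function(r) predictSyndrome(r, "D01", reg2)$syndrome[1])
  expect_identical(p1, p2)
  expect_gte(mean(p1 == y[match(apply(probe, 1, paste, collapse = ","),
                                apply(x, 1, paste, collapse = ","))]), 0.8)
  # ranked list covers the label set; top equals the majority vote
  r1 <- predictSyndrome(probe[1, ], "D01", reg1)
  expect_setequal(r1$syndrome, c("S1", "S2", "S3"))
  expect_true(!is.unsorted(rev(r1$votes)))
  # unknown disease errors
  expect_error(predictSyndrome(probe[1, ], "D99", reg1), "no model")
  # save/load round-trip predicts identically
  d <- withr::local_tempdir()
  saveRegistry(reg1, d)
  reg3 <- loadRegistry(d)
  p3 <- apply(probe, 1, function(r) predictSyndrome(r, "D01", reg3)$syndrome[1])
  expect_identical(p1, p3)
})

test_that("cross-validated evaluation covers degenerate and random data", {
  set.seed(63)
  x <- matrix(rnorm(40), 20, 2)
  # constant labels: every accuracy is 1
  accConst <- evaluateModels(x, rep("only", 20), folds = 5, seed = 1)
  expect_equal(unname(accConst), rep(1, 5))
  expect_named(accConst, c("bp", "svc", "rf", "xgb", "integrated"))
  # random labels on 2 classes: accuracies near chance
  n <- 120
  xr <- matrix(rnorm(n * 3), n, 3); colnames(xr) <- paste0("f", 1:3)
  yr <- sample(c("a", "b"), n, TRUE)
  accRand <- quietly(evaluateModels(xr, yr, folds = 5, seed = 2))
  expect_true(all(accRand > 0.2 & accRand < 0.8))
  # too few records per class reduces the fold count with a warning
  xs <- matrix(rnorm(28), 14, 2); colnames(xs) <- c("f1", "f2")
  ys <- rep(c("a", "b"), c(11, 3))
  expect_warning(evaluateModels(xs, ys, folds = 5, seed = 3), "reducing folds")
})

test_that("the resampled hyperparameter search returns a valid setting", {
  set.seed(64)
  n <- 40
  y <- rep(c("u", "v"), each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3) + 2 * (y == "v")
  colnames(x) <- paste0("f", 1:3)
  m <- quietly(fitIntegrated("D", x, y, seed = 2, tune = TRUE, tuneFolds = 2))
  expect_length(m$learners, 4)
  pr <- tcmdx:::predictBase(m$learners$rf, x)
  expect_gte(mean(pr$labels == y), 0.9)
})
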