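test_that("encoding pads, truncates and maps out-of-vocabulary to pad", {
  vocab <- c(a = 1L, b = 2L, c = 3L)
  expect_equal(cnnEncode(c("a", "b", "c"), 5, vocab), c(1L, 2L, 3L, 0L, 0L))
  expect_equal(cnnEncode(c("a", "b", "c"), 3, vocab), c(1L, 2L, 3L))
  expect_equal(cnnEncode(c("a", "b", "c", "a", "b"), 3, vocab), c(1L, 2L, 3L))
  expect_equal(cnnEncode(c("zz", "a"), 3, vocab), c(0L, 1L, 0L))
})

test_that("feature surface heights follow the valid-convolution formula", {
  expect_equal(convOutputHeight(50, 50), 1L)
  expect_equal(convOutputHeight(50, 49), 2L)  # the published 2x1 surface
  expect_equal(convOutputHeight(50, 48), 3L)
  expect_equal(convOutputHeight(50, 47), 4L)
  expect_equal(convOutputHeight(10, 4), 7L)
  expect_error(convOutputHeight(10, 11), "\\[1, L\\]")
})

test_that("forward passes produce normalized, deterministic distributions", {
  cfg <- textCnnConfig(nClasses = 3, L = 8, d = 6, nFilters = 5, seed = 2)
  params <- tcmdx:::initCnnParams(10, cfg)
  set.seed(7)
  ids <- matrix(sample(0:10, 4 * 8, TRUE), 4, 8)
  out <- tcmdx:::cnnForwardBatch(params, ids, cfg)
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-9)
  out2 <- tcmdx:::cnnForwardBatch(params, ids, cfg)
  expect_identical(out$probs, out2$probs)
  # the pre-pooling feature surface of a height L-1 kernel has 2 rows
  cfg49 <- textCnnConfig(nClasses = 2, L = 50, d = 10, nFilters = 3,
                         kernelHeights = 49L, seed = 1)
  p49 <- tcmdx:::initCnnParams(5, cfg49)
  one <- matrix(c(rep(1L, 20), rep(0L, 30)), 1, 50)
  U <- tcmdx:::unfoldWindows(p49$Emb[t(one) + 1L, , drop = FALSE], 1L, 50L, 10L, 49L)
  expect_equal(nrow(U), convOutputHeight(50, 49))
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- textCnnConfig(nClasses = 3, L = 6, d = 4, nFilters = 3,
                       kernelHeights = c(5L, 4L), seed = 5)
  params <- tcmdx:::initCnnParams(8, cfg)
  set.seed(8)
  ids <- matrix(sample(0:8, 3 * 6, TRUE), 3, 6)
  y <- c(1L, 3L, 2L)
  lossOf <- function(p) {
    pr <- tcmdx:::cnnForwardBatch(p, ids, cfg)$probs
    -mean(log(pr[cbind(seq_len(3), y)]))
  }
  fwd <- tcmdx:::cnnForwardBatch(params, ids, cfg, cache = TRUE)
  gr <- tcmdx:::cnnBackwardBatch(params, ids, y, cfg, fwd)
  eps <- 1e-6
  checks <- list(
    list(get = function(p) p$Wo, set = function(p, v) { p$Wo <- v; p }, g = gr$Wo),
    list(get = function(p) p$W[["5"]], set = function(p, v) { p$W[["5"]] <- v; p },
         g = gr$W[["5"]]),
    list(get = function(p) p$Emb, set = function(p, v) { p$Emb <- v; p }, g = gr$Emb)
  )
  for (ch in checks) {
    m <- ch$get(params)
    i <- which.max(abs(ch$g))
    m2 <- m; m2[i] <- m2[i] + eps
    num <- (lossOf(ch$set(params, m2)) - lossOf(params)) / eps
    expect_equal(ch$g[i], num, tolerance = 1e-4)
  }
})

test_that("fitting a separable corpus reaches high validation accuracy", {
  ont <- smallOntology()
  lex <- makeLexicon(ont)
  notes <- smallCorpus(n = 30, seed = 51, ont = ont, noiseProb = 0)
  recs <- lapply(notes, function(n) quietly(structureRecord(n, lexicon = lex)))
  toks <- lapply(recs, entityTokens)
  dis <- vapply(notes, `[[`, "", "disease")
  set.seed(1)
  ix <- sample(length(notes)); tr <- ix[1:70]; va <- ix[71:90]
  cfg <- textCnnConfig(nClasses = 3, L = 20, d = 24, nFilters = 24,
                       epochs = 10, seed = 6)
  m <- cnnFit(toks[tr], dis[tr], toks[va], dis[va], cfg)
  expect_gte(max(m$valAccTrace), 0.95)
  # same seed twice: identical accuracy trace
  m2 <- cnnFit(toks[tr], dis[tr], toks[va], dis[va], cfg)
  expect_identical(m$valAccTrace, m2$valAccTrace)
  # zero epochs returns the initialization
  cfg0 <- textCnnConfig(nClasses = 3, L = 20, d = 24, nFilters = 24,
                        epochs = 0, seed = 6)
  m0 <- cnnFit(toks[tr], dis[tr], config = cfg0)
  expect_identical(m0$params, tcmdx:::initCnnParams(length(m0$vocab), cfg0))
  # a class missing from training errors
  expect_error(cnnFit(toks[tr], dis[tr], config = cfg,
                      classes = c("D01", "D02", "D03", "ghost")),
               "absent")
})

test_that("top-k output is a ranked prefix chain with tie-breaks by index", {
  ont <- smallOntology()
  lex <- makeLexicon(ont)
  notes <- smallCorpus(n = 10, seed = 52, ont = ont)
  recs <- lapply(notes, function(n) quietly(structureRecord(n, lexicon = lex)))
  toks <- lapply(recs, entityTokens)
  dis <- vapply(notes, `[[`, "", "disease")
  cfg <- textCnnConfig(nClasses = 3, L = 20, d = 12, nFilters = 8,
                       epochs = 2, seed = 3)
  m <- quietly(cnnFit(toks, dis, config = cfg))
  p5 <- predictTopk(m, toks[[1]], 5)
  expect_equal(nrow(p5), 3)  # truncated at nClasses
  expect_equal(sum(p5$probability), 1, tolerance = 1e-6)
  expect_true(all(diff(p5$probability) <= 1e-12))
  p1 <- predictTopk(m, toks[[1]], 1)
  p3 <- predictTopk(m, toks[[1]], 3)
  expect_equal(p1$disease, p3$disease[1])
  expect_equal(p3$disease, p5$disease[1:3])
})
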