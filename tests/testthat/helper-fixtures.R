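# Shared fixtures and independent oracles, all built in code.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

smallOntology <- function(seed = 2L) buildOntology(3L, 5L, 2, seed = seed)

smallCorpus <- function(n = 20L, seed = 5L, ont = smallOntology(), ...) {
  counts <- stats::setNames(rep(n, length(ont$diseases)), ont$diseases)
  quietly(generateCorpus(genConfig(ont, counts, seed = seed, ...)))
}

# independent brute-force CRF oracle: direct summation over one path and
# exhaustive enumeration over all K^T paths (never calls the package's
# forward/Viterbi code)
bruteForcePathScore <- function(e, A, y) {
  K <- ncol(e); T_ <- nrow(e)
  s <- A[K + 1L, y[1L]] + A[y[T_], K + 2L]
  for (t in seq_len(T_)) s <- s + e[t, y[t]]
  if (T_ > 1L) for (t in seq_len(T_ - 1L)) s <- s + A[y[t], y[t + 1L]]
  s
}

bruteForceAllScores <- function(e, A) {
  K <- ncol(e); T_ <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  apply(paths, 1L, function(y) bruteForcePathScore(e, A, as.integer(y)))
}

randomCrfInstance <- function(Tmax = 4L, Kmax = 3L) {
  T_ <- sample.int(Tmax, 1L); K <- sample.int(Kmax, 1L)
  e <- matrix(stats::rnorm(T_ * K, sd = 2), T_, K)
  A <- matrix(stats::rnorm((K + 2L)^2), K + 2L, K + 2L)
  A[, K + 1L] <- -Inf
  A[K + 2L, ] <- -Inf
  list(e = e, A = A, T_ = T_, K = K)
}

# enumeration oracle for the majority-vote tie-break chain:
# votes desc -> mean voter confidence desc -> label asc
bruteForceVote <- function(labels, confidences) {
  cand <- sort(unique(labels))
  votes <- vapply(cand, function(l) sum(labels == l), 0L)
  conf <- vapply(cand, function(l) mean(confidences[labels == l]), 0)
  cand[order(-votes, -conf, cand)][1L]
}
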