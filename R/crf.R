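#' BIO tag scheme for a set of entity types
#'
#' Tags are ordered `O`, then `B-t`, `I-t` per entity type, indexed 1..K;
#' two virtual indices K+1 (START) and K+2 (STOP) frame the transition
#' matrix. Transitions into START and out of STOP are impossible (-Inf).
#'
#' @param entityTypes character vector of entity types.
#' @return a `tcmTagScheme`: list with `tags`, `index` (named integer),
#'   `K`, `start`, `stop`.
#' @export
tagScheme <- function(entityTypes = tcmEntityTypes()) {
  stopifnot(length(entityTypes) >= 1L, !anyDuplicated(entityTypes))
  tags <- c("O", as.vector(rbind(paste0("B-", entityTypes),
                                 paste0("I-", entityTypes))))
  K <- length(tags)
  structure(
    list(tags = tags, index = stats::setNames(seq_len(K), tags),
         K = K, start = K + 1L, stop = K + 2L),
    class = "tcmTagScheme"
  )
}

# a fresh transition matrix honoring the START/STOP constraints
newTransitions <- function(K, init = 0) {
  A <- matrix(init, K + 2L, K + 2L)
  A[, K + 1L] <- -Inf   # nothing enters START
  A[K + 2L, ] <- -Inf   # nothing leaves STOP
  A[K + 1L, K + 1L] <- -Inf
  A
}

checkCrfArgs <- function(e, A) {
  stopifnot(is.matrix(e), is.matrix(A))
  K <- ncol(e)
  if (nrow(A) != K + 2L || ncol(A) != K + 2L) {
    stop("transition matrix must be (K+2) x (K+2) for K emission columns",
         call. = FALSE)
  }
  if (nrow(e) > 0L && !all(is.finite(e))) stop("emissions must be finite", call. = FALSE)
  K
}

#' Score one tag path under a linear-chain CRF
#'
#' The unnormalized log-score of tag sequence `y`: the sum of per-token
#' emission scores plus the START->y1, y_t->y_{t+1} and y_T->STOP transition
#' scores.
#'
#' @param e emission matrix, T x K.
#' @param A transition matrix, (K+2) x (K+2); rows/cols K+1 and K+2 are the
#'   virtual START and STOP states.
#' @param y integer tag sequence of length T (values in 1..K).
#' @return a single numeric score.
#' @export
crfPathScore <- function(e, A, y) {
  K <- checkCrfArgs(e, A)
  T_ <- nrow(e)
  if (length(y) != T_) stop("tag sequence length must equal nrow(e)", call. = FALSE)
  if (T_ == 0L) return(0)
  if (any(y < 1L | y > K)) stop("tag indices out of range", call. = FALSE)
  s <- sum(e[cbind(seq_len(T_), y)]) + A[K + 1L, y[1L]] + A[y[T_], K + 2L]
  if (T_ > 1L) s <- s + sum(A[cbind(y[-T_], y[-1L])])
  s
}

#' Log-partition function of a linear-chain CRF
#'
#' The forward algorithm in log space: log of the sum over all K^T tag paths
#' of `exp(crfPathScore)`.
#'
#' @inheritParams crfPathScore
#' @return a single numeric value; always >= any single path score.
#' @export
crfLogPartition <- function(e, A) {
  K <- checkCrfArgs(e, A)
  T_ <- nrow(e)
  if (T_ == 0L) return(0)
  alpha <- A[K + 1L, seq_len(K)] + e[1L, ]
  if (T_ > 1L) {
    Ain <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in 2:T_) {
      alpha <- apply(Ain + alpha, 2L, logSumExp) + e[t, ]
    }
  }
  logSumExp(alpha + A[seq_len(K), K + 2L])
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns the highest-scoring tag path and its score. Ties at any
#' backpointer are broken toward the lowest tag index, making the decode
#' deterministic.
#'
#' @inheritParams crfPathScore
#' @return list with `tags` (integer vector, length T) and `score`
#'   (= `crfPathScore(e, A, tags)`).
#' @export
crfViterbi <- function(e, A) {
  K <- checkCrfArgs(e, A)
  T_ <- nrow(e)
  if (T_ == 0L) return(list(tags = integer(0), score = 0))
  delta <- A[K + 1L, seq_len(K)] + e[1L, ]
  back <- matrix(0L, T_, K)
  if (T_ > 1L) {
    Ain <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in 2:T_) {
      cand <- Ain + delta            # cand[i, j]: arrive at j from i
      bp <- apply(cand, 2L, which.max)  # which.max: first (lowest) index wins
      delta <- cand[cbind(bp, seq_len(K))] + e[t, ]
      back[t, ] <- bp
    }
  }
  final <- delta + A[seq_len(K), K + 2L]
  yT <- which.max(final)
  tags <- integer(T_)
  tags[T_] <- yT
  if (T_ > 1L) {
    for (t in T_:2) tags[t - 1L] <- back[t, tags[t]]
  }
  list(tags = tags, score = unname(final[yT]))
}

# forward-backward: log Z, per-token tag marginals (T x K) and expected
# transition counts ((K+2) x (K+2)) -- the sufficient statistics for the
# gradient of the negative log-likelihood
crfForwardBackward <- function(e, A) {
  K <- checkCrfArgs(e, A)
  T_ <- nrow(e)
  ks <- seq_len(K)
  if (T_ == 0L) {
    return(list(logZ = 0, marginals = matrix(0, 0, K),
                expTrans = matrix(0, K + 2L, K + 2L)))
  }
  Ain <- A[ks, ks, drop = FALSE]
  alpha <- matrix(-Inf, T_, K)
  alpha[1L, ] <- A[K + 1L, ks] + e[1L, ]
  if (T_ > 1L) {
    for (t in 2:T_) {
      alpha[t, ] <- apply(Ain + alpha[t - 1L, ], 2L, logSumExp) + e[t, ]
    }
  }
  logZ <- logSumExp(alpha[T_, ] + A[ks, K + 2L])
  beta <- matrix(-Inf, T_, K)
  beta[T_, ] <- A[ks, K + 2L]
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      # beta[t, i] = logsum_j A[i,j] + e[t+1,j] + beta[t+1,j]
      tmp <- sweep(Ain, 2L, e[t + 1L, ] + beta[t + 1L, ], `+`)
      beta[t, ] <- apply(tmp, 1L, logSumExp)
    }
  }
  marg <- exp(alpha + beta - logZ)
  expTrans <- matrix(0, K + 2L, K + 2L)
  expTrans[K + 1L, ks] <- exp(A[K + 1L, ks] + e[1L, ] + beta[1L, ] - logZ)
  expTrans[ks, K + 2L] <- exp(alpha[T_, ] + A[ks, K + 2L] - logZ)
  if (T_ > 1L) {
    for (t in 1:(T_ - 1L)) {
      P <- outer(alpha[t, ], e[t + 1L, ] + beta[t + 1L, ], `+`) + Ain
      expTrans[ks, ks] <- expTrans[ks, ks] + exp(P - logZ)
    }
  }
  list(logZ = logZ, marginals = marg, expTrans = expTrans)
}

#' Negative log-likelihood of gold tag paths under a CRF
#'
#' Sum over a batch of `crfLogPartition(e, A) - crfPathScore(e, A, gold)`;
#' non-negative by construction.
#'
#' @param emissions list of T_i x K emission matrices.
#' @param A shared transition matrix.
#' @param gold list of integer tag sequences, `length(gold[[i]]) == T_i`.
#' @return a single numeric value >= 0.
#' @export
crfNll <- function(emissions, A, gold) {
  stopifnot(length(emissions) == length(gold))
  s <- 0
  for (i in seq_along(emissions)) {
    s <- s + crfLogPartition(emissions[[i]], A) -
      crfPathScore(emissions[[i]], A, gold[[i]])
  }
  s
}
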