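#' Text-convolution classifier configuration
#'
#' The classifier embeds a length-`L` (zero-padded) token sequence into an
#' `L x d` matrix and convolves it with `nFilters` kernels per height; each
#' kernel spans the full embedding width, so a height-`h` kernel yields an
#' `(L - h + 1) x 1` feature surface that is max-pooled to a scalar. The
#' pooled vector feeds a fully connected softmax layer over the diseases and
#' the top-k ranked classes are reported. Defaults follow the published
#' geometry: 100-dimensional embeddings and 256 kernels at heights L-1, L-2
#' and L-3 (giving 2x1, 3x1 and 4x1 surfaces); the classic small heights
#' (2, 3, 4) remain available via `kernelHeights`.
#'
#' @param nClasses number of disease classes (>= 2).
#' @param L maximum tokens per note; shorter inputs are zero-padded, longer
#'   ones truncated.
#' @param d embedding dimension.
#' @param nFilters convolution kernels per height.
#' @param kernelHeights integer vector of kernel heights, all <= L.
#' @param epochs,lr,batchSize,patience Adam training settings.
#' @param seed integer seed.
#' @return a `tcmCnnConfig`.
#' @export
textCnnConfig <- function(nClasses, L = 50L, d = 100L, nFilters = 256L,
                          kernelHeights = c(L - 1L, L - 2L, L - 3L),
                          epochs = 20L, lr = 0.01, batchSize = 64L,
                          patience = 4L, seed = 1L) {
  stopifnot(nClasses >= 2L, L >= 1L, d >= 1L, nFilters >= 1L)
  kernelHeights <- as.integer(kernelHeights)
  if (any(kernelHeights < 1L) || max(kernelHeights) > L) {
    stop("kernel heights must lie in [1, L]", call. = FALSE)
  }
  structure(list(nClasses = as.integer(nClasses), L = as.integer(L),
                 d = as.integer(d), nFilters = as.integer(nFilters),
                 kernelHeights = kernelHeights, epochs = as.integer(epochs),
                 lr = lr, batchSize = as.integer(batchSize),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "tcmCnnConfig")
}

#' Feature-surface height of a valid stride-1 convolution
#'
#' A kernel of height `h` (and width equal to the embedding dimension) slid
#' over a length-`L` embedded sequence produces `L - h + 1` output rows; at
#' `h = L - 1` that is the published 2x1 surface.
#'
#' @param L input length in tokens.
#' @param h kernel height, `1 <= h <= L`.
#' @return integer number of output rows.
#' @export
#' @examples
#' convOutputHeight(50, 49) # 2
convOutputHeight <- function(L, h) {
  stopifnot(L >= 1L)
  if (any(h < 1L) || any(h > L)) stop("kernel height must lie in [1, L]", call. = FALSE)
  as.integer(L - h + 1L)
}

#' Encode tokens as a fixed-length index sequence
#'
#' Tokens are mapped through the vocabulary, truncated at `L` and
#' right-padded with the pad index 0 (whose embedding row is fixed at zero).
#' Out-of-vocabulary tokens also map to 0.
#'
#' @param tokens character vector.
#' @param L target length.
#' @param vocab named integer vector, token -> index (1-based).
#' @return integer vector of length `L`.
#' @export
cnnEncode <- function(tokens, L, vocab) {
  stopifnot(L >= 1L)
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- 0L
  ids <- utils::head(ids, L)
  c(ids, rep(0L, L - length(ids)))
}

initCnnParams <- function(V, config) {
  withSeed(config$seed, {
    d <- config$d; F_ <- config$nFilters
    Emb <- matrix(stats::rnorm((V + 1L) * d, sd = 0.1), V + 1L, d)
    Emb[1L, ] <- 0  # pad row
    W <- list(); b <- list()
    for (h in config$kernelHeights) {
      key <- as.character(h)
      W[[key]] <- matrix(stats::rnorm(h * d * F_, sd = sqrt(2 / (h * d))), h * d, F_)
      b[[key]] <- numeric(F_)
    }
    nh <- length(config$kernelHeights)
    Wo <- matrix(stats::rnorm(nh * F_ * config$nClasses, sd = sqrt(1 / (nh * F_))),
                 nh * F_, config$nClasses)
    bo <- numeric(config$nClasses)
    list(Emb = Emb, W = W, b = b, Wo = Wo, bo = bo)
  })
}

# flatten convolution windows: rows = (sample-major, window-minor)
unfoldWindows <- function(Xb, B, L, d, h) {
  nw <- L - h + 1L
  U <- matrix(0, B * nw, h * d)
  base <- rep((seq_len(B) - 1L) * L, each = nw) + rep(seq_len(nw), B)
  for (j in seq_len(h)) {
    U[, ((j - 1L) * d + 1L):(j * d)] <- Xb[base + j - 1L, , drop = FALSE]
  }
  U
}

softmaxRows <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# forward pass over a batch of encoded sequences; keeps intermediates when
# `cache` so the backward pass can reuse them
cnnForwardBatch <- function(params, ids, config, cache = FALSE) {
  B <- nrow(ids); L <- config$L; d <- config$d; F_ <- config$nFilters
  Xb <- params$Emb[t(ids) + 1L, , drop = FALSE]  # (B*L) x d, sample-major
  pooled <- matrix(0, B, 0)
  inter <- list()
  for (h in config$kernelHeights) {
    key <- as.character(h)
    nw <- L - h + 1L
    U <- unfoldWindows(Xb, B, L, d, h)
    Zpre <- U %*% params$W[[key]] +
      matrix(params$b[[key]], B * nw, F_, byrow = TRUE)
    Z <- pmax(Zpre, 0)
    # max-pool over the nw window positions of each sample
    firstRows <- (seq_len(B) - 1L) * nw + 1L
    pm <- Z[firstRows, , drop = FALSE]
    am <- matrix(1L, B, F_)
    if (nw > 1L) {
      for (w in 2:nw) {
        cand <- Z[firstRows + w - 1L, , drop = FALSE]
        better <- cand > pm
        pm[better] <- cand[better]
        am[better] <- w
      }
    }
    pooled <- cbind(pooled, pm)
    if (cache) inter[[key]] <- list(U = U, Zpre = Zpre, am = am, nw = nw)
  }
  logits <- pooled %*% params$Wo + matrix(params$bo, B, config$nClasses, byrow = TRUE)
  probs <- softmaxRows(logits)
  out <- list(probs = probs, pooled = pooled)
  if (cache) { out$inter <- inter; out$Xb <- Xb }
  out
}

cnnBackwardBatch <- function(params, ids, y, config, fwd) {
  B <- nrow(ids); d <- config$d; F_ <- config$nFilters; L <- config$L
  dLogits <- fwd$probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  dWo <- t(fwd$pooled) %*% dLogits
  dbo <- colSums(dLogits)
  dPooled <- dLogits %*% t(params$Wo)
  dXb <- matrix(0, nrow(fwd$Xb), d)
  dW <- list(); db <- list()
  off <- 0L
  for (h in config$kernelHeights) {
    key <- as.character(h)
    it <- fwd$inter[[key]]
    nw <- it$nw
    dPh <- dPooled[, (off + 1L):(off + F_), drop = FALSE]
    off <- off + F_
    dZ <- matrix(0, B * nw, F_)
    rowIdx <- as.vector(it$am + (seq_len(B) - 1L) * nw)
    colIdx <- rep(seq_len(F_), each = B)
    dZ[cbind(rowIdx, colIdx)] <- as.vector(dPh)
    dZ[it$Zpre <= 0] <- 0
    dW[[key]] <- t(it$U) %*% dZ
    db[[key]] <- colSums(dZ)
    dU <- dZ %*% t(params$W[[key]])
    base <- rep((seq_len(B) - 1L) * L, each = nw) + rep(seq_len(nw), B)
    for (j in seq_len(h)) {
      rows <- base + j - 1L
      seg <- dU[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
      dXb[rows, ] <- dXb[rows, ] + seg
    }
  }
  # scatter token gradients into the embedding table; pad row stays zero
  grp <- as.vector(t(ids)) + 1L
  agg <- rowsum(dXb, group = grp)
  dEmb <- 0 * params$Emb
  gi <- as.integer(rownames(agg))
  dEmb[gi, ] <- agg
  dEmb[1L, ] <- 0
  list(Emb = dEmb, W = dW, b = db, Wo = dWo, bo = dbo)
}

# flat-list Adam over the nested parameter structure
flatCnn <- function(x) {
  fp <- list(Emb = x$Emb, Wo = x$Wo, bo = x$bo)
  for (key in names(x$W)) {
    fp[[paste0("W.", key)]] <- x$W[[key]]
    fp[[paste0("b.", key)]] <- x$b[[key]]
  }
  fp
}

cnnAdam <- function(params, grads, state, lr) {
  st <- adamStep(flatCnn(params), flatCnn(grads), state, lr)
  params$Emb <- st$params$Emb
  params$Emb[1L, ] <- 0
  for (key in names(params$W)) {
    params$W[[key]] <- st$params[[paste0("W.", key)]]
    params$b[[key]] <- st$params[[paste0("b.", key)]]
  }
  params$Wo <- st$params$Wo
  params$bo <- st$params$bo
  list(params = params, state = st$state)
}

#' Fit the text-convolution disease classifier
#'
#' Cross-entropy training with Adam on minibatches; early stopping keeps the
#' parameters with the best validation top-1 accuracy. With `epochs = 0` the
#' initialized (untrained) model is returned.
#'
#' @param tokensList list of token sequences (training notes).
#' @param labels disease label per training note; every class in `classes`
#'   must be represented.
#' @param valTokensList,valLabels validation notes (may be empty).
#' @param config a [textCnnConfig()].
#' @param classes class inventory; defaults to the sorted unique training
#'   labels.
#' @return a `tcmCnnModel` with the embedded config, vocabulary, class
#'   labels, parameters and the per-epoch validation accuracy trace.
#' @export
cnnFit <- function(tokensList, labels, valTokensList = list(),
                   valLabels = character(0), config, classes = sort(unique(labels))) {
  stopifnot(inherits(config, "tcmCnnConfig"), length(tokensList) == length(labels))
  if (!all(classes %in% labels)) {
    stop("class(es) absent from training data: ",
         paste(setdiff(classes, labels), collapse = ", "), call. = FALSE)
  }
  if (length(classes) != config$nClasses) {
    stop("config$nClasses does not match the class inventory", call. = FALSE)
  }
  vocabTokens <- unique(unlist(tokensList, use.names = FALSE))
  vocab <- stats::setNames(seq_along(vocabTokens), vocabTokens)
  enc <- t(vapply(tokensList, cnnEncode, integer(config$L), L = config$L, vocab = vocab))
  y <- match(labels, classes)
  params <- initCnnParams(length(vocab), config)
  model <- structure(list(params = params, vocab = vocab, classes = classes,
                          config = config, valAccTrace = numeric(0)),
                     class = "tcmCnnModel")
  if (config$epochs == 0L) return(model)
  encVal <- if (length(valTokensList)) {
    t(vapply(valTokensList, cnnEncode, integer(config$L), L = config$L, vocab = vocab))
  } else NULL
  state <- adamInit(flatCnn(params))
  best <- list(acc = -Inf, params = params, since = 0L)
  withSeed(config$seed + 1L, {
    n <- length(tokensList)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = config$batchSize)) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        fwd <- cnnForwardBatch(params, enc[idx, , drop = FALSE], config, cache = TRUE)
        gr <- cnnBackwardBatch(params, enc[idx, , drop = FALSE], y[idx], config, fwd)
        st <- cnnAdam(params, gr, state, config$lr)
        params <- st$params; state <- st$state
      }
      model$params <- params
      acc <- if (!is.null(encVal)) {
        pv <- cnnForwardBatch(params, encVal, config)$probs
        mean(classes[max.col(pv, ties.method = "first")] == valLabels)
      } else NA_real_
      model$valAccTrace <- c(model$valAccTrace, acc)
      if (!is.na(acc)) {
        if (acc > best$acc + 1e-9) {
          best$acc <- acc; best$params <- params; best$since <- 0L
        } else {
          best$since <- best$since + 1L
          if (best$since >= config$patience) break
        }
        if (acc >= 0.9999) break
      }
    }
  })
  if (!is.null(encVal) && is.finite(best$acc)) model$params <- best$params
  model
}

#' @export
print.tcmCnnModel <- function(x, ...) {
  cat(sprintf("tcmCnnModel: %d classes, |V|=%d, L=%d, d=%d, %d filters x heights {%s}\n",
              length(x$classes), length(x$vocab), x$config$L, x$config$d,
              x$config$nFilters, paste(x$config$kernelHeights, collapse = ",")))
  if (length(x$valAccTrace)) {
    cat("  val top-1 trace:", paste(sprintf("%.3f", x$valAccTrace), collapse = " "), "\n")
  }
  invisible(x)
}

#' Class distribution for one token sequence
#' @param model a `tcmCnnModel`.
#' @param tokens character vector.
#' @return named numeric probabilities over classes (sums to 1).
#' @export
cnnPredictProbs <- function(model, tokens) {
  ids <- matrix(cnnEncode(tokens, model$config$L, model$vocab), 1L)
  p <- cnnForwardBatch(model$params, ids, model$config)$probs[1L, ]
  stats::setNames(p, model$classes)
}

#' Ranked top-k disease prediction
#'
#' Classes ordered by probability (descending), ties broken by class index;
#' truncated to `min(k, nClasses)` entries. `predictTopk(k')` is a prefix of
#' `predictTopk(k)` for `k' <= k`.
#'
#' @param model a `tcmCnnModel`.
#' @param tokens token sequence of one note.
#' @param k ranked list length (>= 1).
#' @return data.frame `disease`, `probability`, in rank order.
#' @export
predictTopk <- function(model, tokens, k = 5L) {
  stopifnot(k >= 1L)
  p <- cnnPredictProbs(model, tokens)
  ord <- orderDesc(unname(p))
  take <- utils::head(ord, k)
  data.frame(disease = model$classes[take], probability = unname(p)[take],
             stringsAsFactors = FALSE)
}

#' Small grid search over classifier hyperparameters
#'
#' Fits one model per configuration and keeps the one with the best
#' validation top-1 accuracy (ties to the earlier configuration).
#'
#' @param tokensList,labels,valTokensList,valLabels as in [cnnFit()].
#' @param configs list of [textCnnConfig()] objects.
#' @return the best `tcmCnnModel`, with the grid's accuracies in
#'   `$gridAccuracies`.
#' @export
cnnGridSearch <- function(tokensList, labels, valTokensList, valLabels, configs) {
  stopifnot(length(configs) >= 1L)
  accs <- numeric(length(configs))
  best <- NULL
  for (i in seq_along(configs)) {
    m <- cnnFit(tokensList, labels, valTokensList, valLabels, configs[[i]])
    accs[i] <- if (length(m$valAccTrace)) max(m$valAccTrace, na.rm = TRUE) else NA_real_
    if (is.null(best) || (!is.na(accs[i]) && accs[i] > best$acc + 1e-9)) {
      best <- list(model = m, acc = accs[i])
    }
  }
  best$model$gridAccuracies <- accs
  best$model
}
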