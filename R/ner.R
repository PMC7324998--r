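#' NER model configuration
#'
#' @param embedDim token embedding dimension.
#' @param hiddenDim hidden units per direction of the recurrent encoder.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience epochs without validation span-F1 improvement before
#'   early stopping.
#' @param maxSequences cap on training sequences per epoch (sections are the
#'   sequence unit); `Inf` uses everything.
#' @param seed integer seed governing initialization and shuffling.
#' @return a list of class `tcmNerConfig`.
#' @export
nerConfig <- function(embedDim = 16L, hiddenDim = 16L, epochs = 8L, lr = 0.05,
                      patience = 3L, maxSequences = Inf, seed = 1L) {
  structure(list(embedDim = as.integer(embedDim), hiddenDim = as.integer(hiddenDim),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience), maxSequences = maxSequences,
                 seed = as.integer(seed)),
            class = "tcmNerConfig")
}

# sections carrying entity annotations (the structured pages are excluded)
narrativeSections <- function() setdiff(tcmSections(), c("admission", "discharge"))

# one training sequence per non-empty narrative section
nerSequences <- function(notes, scheme) {
  seqs <- list()
  for (note in notes) {
    for (nm in intersect(names(note$sections), narrativeSections())) {
      txt <- normalizeWidth(note$sections[[nm]])
      tok <- tokenizeWithOffsets(txt)
      if (nrow(tok) == 0L) next
      sp <- note$spans[note$spans$section == nm, , drop = FALSE]
      tags <- bioTags(tok, sp)
      seqs[[length(seqs) + 1L]] <- list(tokens = tok$token,
                                        tags = unname(scheme$index[tags]))
    }
  }
  seqs
}

initNerParams <- function(V, d, H, K, seed) {
  withSeed(seed, {
    rnorm_m <- function(r, c, sd) matrix(stats::rnorm(r * c, sd = sd), r, c)
    list(
      Emb = rnorm_m(V + 1L, d, 0.1),   # row 1 = <unk>
      Wf = rnorm_m(H, d, 1 / sqrt(d)), Uf = rnorm_m(H, H, 1 / sqrt(H)), bf = numeric(H),
      Wb = rnorm_m(H, d, 1 / sqrt(d)), Ub = rnorm_m(H, H, 1 / sqrt(H)), bb = numeric(H),
      P = rnorm_m(K, 2L * H, 1 / sqrt(2 * H)), q = numeric(K),
      A = newTransitions(K, init = 0)
    )
  })
}

# encoder forward pass: returns hidden states and emissions for one sequence
nerForward <- function(params, ids) {
  T_ <- length(ids)
  d <- ncol(params$Emb); H <- nrow(params$Wf)
  X <- params$Emb[ids + 1L, , drop = FALSE]  # +1: row 1 is <unk> (id 0)
  hf <- matrix(0, T_, H); hb <- matrix(0, T_, H)
  prev <- numeric(H)
  for (t in seq_len(T_)) {
    prev <- tanh(params$Wf %*% X[t, ] + params$Uf %*% prev + params$bf)[, 1L]
    hf[t, ] <- prev
  }
  nxt <- numeric(H)
  for (t in rev(seq_len(T_))) {
    nxt <- tanh(params$Wb %*% X[t, ] + params$Ub %*% nxt + params$bb)[, 1L]
    hb[t, ] <- nxt
  }
  Hm <- cbind(hf, hb)
  e <- Hm %*% t(params$P) + matrix(params$q, T_, length(params$q), byrow = TRUE)
  list(X = X, hf = hf, hb = hb, H = Hm, e = e)
}

# gradients of the CRF negative log-likelihood for one sequence
nerGradients <- function(params, ids, gold, fwd) {
  K <- length(params$q); H <- nrow(params$Wf); T_ <- length(ids)
  fb <- crfForwardBackward(fwd$e, params$A)
  de <- fb$marginals
  de[cbind(seq_len(T_), gold)] <- de[cbind(seq_len(T_), gold)] - 1
  dA <- fb$expTrans
  ks <- seq_len(K)
  dA[K + 1L, gold[1L]] <- dA[K + 1L, gold[1L]] - 1
  dA[gold[T_], K + 2L] <- dA[gold[T_], K + 2L] - 1
  if (T_ > 1L) {
    for (t in seq_len(T_ - 1L)) {
      dA[gold[t], gold[t + 1L]] <- dA[gold[t], gold[t + 1L]] - 1
    }
  }
  dP <- t(de) %*% fwd$H
  dq <- colSums(de)
  dH <- de %*% params$P
  dX <- matrix(0, T_, ncol(params$Emb))
  dWf <- 0 * params$Wf; dUf <- 0 * params$Uf; dbf <- numeric(H)
  carry <- numeric(H)
  for (t in rev(seq_len(T_))) {
    dz <- (dH[t, seq_len(H)] + carry) * (1 - fwd$hf[t, ]^2)
    dWf <- dWf + outer(dz, fwd$X[t, ])
    hprev <- if (t > 1L) fwd$hf[t - 1L, ] else numeric(H)
    dUf <- dUf + outer(dz, hprev)
    dbf <- dbf + dz
    dX[t, ] <- dX[t, ] + as.numeric(t(params$Wf) %*% dz)
    carry <- as.numeric(t(params$Uf) %*% dz)
  }
  dWb <- 0 * params$Wb; dUb <- 0 * params$Ub; dbb <- numeric(H)
  carry <- numeric(H)
  for (t in seq_len(T_)) {
    dz <- (dH[t, H + seq_len(H)] + carry) * (1 - fwd$hb[t, ]^2)
    dWb <- dWb + outer(dz, fwd$X[t, ])
    hnxt <- if (t < T_) fwd$hb[t + 1L, ] else numeric(H)
    dUb <- dUb + outer(dz, hnxt)
    dbb <- dbb + dz
    dX[t, ] <- dX[t, ] + as.numeric(t(params$Wb) %*% dz)
    carry <- as.numeric(t(params$Ub) %*% dz)
  }
  dEmb <- 0 * params$Emb
  for (t in seq_len(T_)) {
    dEmb[ids[t] + 1L, ] <- dEmb[ids[t] + 1L, ] + dX[t, ]
  }
  list(grads = list(Emb = dEmb, Wf = dWf, Uf = dUf, bf = dbf,
                    Wb = dWb, Ub = dUb, bb = dbb, P = dP, q = dq, A = dA),
       loss = fb$logZ - crfPathScore(fwd$e, params$A, gold))
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (nm == "A") {
      mask <- is.finite(params$A)
      g[!mask] <- 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- lr * mh / (sqrt(vh) + eps)
    if (nm == "A") upd[!is.finite(params$A)] <- 0
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

#' Fit the sequence-labeling NER model
#'
#' Trains a bidirectional recurrent (tanh) encoder with a linear-chain CRF
#' output layer by minimizing the CRF negative log-likelihood with Adam,
#' one section-sequence at a time. Early stopping monitors span-level F1 on
#' the validation notes; the best-scoring parameters are kept.
#'
#' @param trainNotes,valNotes lists of `tcmNote` with gold spans.
#' @param config a [nerConfig()].
#' @param entityTypes entity inventory (defaults to [tcmEntityTypes()]).
#' @return a `tcmNerModel`: parameters, vocabulary, tag scheme, config and the
#'   per-epoch validation F1 trace.
#' @export
nerFit <- function(trainNotes, valNotes = list(), config = nerConfig(),
                   entityTypes = tcmEntityTypes()) {
  if (length(trainNotes) == 0L) stop("empty training set", call. = FALSE)
  scheme <- tagScheme(entityTypes)
  seqs <- nerSequences(trainNotes, scheme)
  if (length(seqs) == 0L) stop("no non-empty training sequences", call. = FALSE)
  vocabTokens <- unique(unlist(lapply(seqs, `[[`, "tokens"), use.names = FALSE))
  vocab <- stats::setNames(seq_along(vocabTokens), vocabTokens)  # ids 1..V; 0 = <unk>
  ids <- lapply(seqs, function(s) {
    v <- unname(vocab[s$tokens]); v[is.na(v)] <- 0L; as.integer(v)
  })
  golds <- lapply(seqs, `[[`, "tags")
  params <- initNerParams(length(vocab), config$embedDim, config$hiddenDim,
                          scheme$K, config$seed)
  model <- structure(list(params = params, vocab = vocab, scheme = scheme,
                          config = config, valF1Trace = numeric(0)),
                     class = "tcmNerModel")
  if (config$epochs == 0L) return(model)
  state <- adamInit(params)
  best <- list(f1 = -Inf, params = params, sinceImproved = 0L)
  withSeed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(ids))
      if (is.finite(config$maxSequences) && length(ord) > config$maxSequences) {
        ord <- ord[seq_len(config$maxSequences)]
      }
      for (i in ord) {
        fwd <- nerForward(params, ids[[i]])
        gr <- nerGradients(params, ids[[i]], golds[[i]], fwd)
        st <- adamStep(params, gr$grads, state, config$lr)
        params <- st$params; state <- st$state
      }
      model$params <- params
      f1 <- if (length(valNotes)) {
        mean_f1 <- nerEvaluate(model, valNotes)$f1
        mean_f1
      } else NA_real_
      model$valF1Trace <- c(model$valF1Trace, f1)
      if (!is.na(f1)) {
        if (f1 > best$f1 + 1e-9) {
          best$f1 <- f1; best$params <- params; best$sinceImproved <- 0L
        } else {
          best$sinceImproved <- best$sinceImproved + 1L
          if (best$sinceImproved >= config$patience) break
        }
        if (f1 >= 0.9999) break
      }
    }
  })
  if (length(valNotes) && is.finite(best$f1)) model$params <- best$params
  model
}

#' @export
print.tcmNerModel <- function(x, ...) {
  cat(sprintf("tcmNerModel: |V|=%d, d=%d, H=%d, K=%d tags; val F1 trace: %s\n",
              length(x$vocab), x$config$embedDim, x$config$hiddenDim,
              x$scheme$K,
              if (length(x$valF1Trace)) paste(sprintf("%.3f", x$valF1Trace), collapse = " ")
              else "(none)"))
  invisible(x)
}

#' Decode BIO tags into entity spans
#'
#' Maximal `B-t (I-t)*` runs become spans over token positions (0-based,
#' half-open); an `I-t` not preceded by a `B-t` or `I-t` of the same type is
#' repaired to `B-t`; `O` yields nothing.
#'
#' @param tags character vector of BIO tags.
#' @return data.frame with `start`, `end`, `type` (token coordinates).
#' @export
#' @examples
#' decodeEntities(c("B-symptom", "I-symptom", "O"))
decodeEntities <- function(tags) {
  known <- grepl("^O$|^[BI]-", tags)
  if (!all(known)) stop("unknown tag: ", tags[which(!known)[1]], call. = FALSE)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  curType <- NULL; curStart <- NA_integer_
  closeRun <- function(i) {
    if (!is.null(curType)) {
      starts <<- c(starts, curStart); ends <<- c(ends, i - 1L)
      types <<- c(types, curType)
    }
    curType <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      closeRun(i)
    } else {
      ty <- substring(tg, 3L)
      if (startsWith(tg, "B-") || is.null(curType) || curType != ty) {
        closeRun(i)           # orphan I-t starts a new span (repair to B-t)
        curType <- ty; curStart <- i - 1L
      }
    }
  }
  closeRun(length(tags) + 1L)
  data.frame(start = starts, end = ends, type = types, stringsAsFactors = FALSE)
}

#' Predict entity spans for a note
#'
#' Runs the encoder and Viterbi decoding per narrative section and converts
#' token spans back to character offsets in the (width-normalized) section
#' text.
#'
#' @param model a `tcmNerModel`.
#' @param note a `tcmNote` (gold spans, if any, are ignored).
#' @return data.frame `section`, `start`, `end`, `type`, `surface`.
#' @export
nerPredict <- function(model, note) {
  out <- list()
  for (nm in intersect(names(note$sections), narrativeSections())) {
    txt <- normalizeWidth(note$sections[[nm]])
    tok <- tokenizeWithOffsets(txt)
    if (nrow(tok) == 0L) next
    v <- unname(model$vocab[tok$token]); v[is.na(v)] <- 0L
    fwd <- nerForward(model$params, as.integer(v))
    vit <- crfViterbi(fwd$e, model$params$A)
    sp <- decodeEntities(model$scheme$tags[vit$tags])
    if (nrow(sp)) {
      out[[nm]] <- data.frame(
        section = nm,
        start = tok$start[sp$start + 1L],
        end = tok$end[sp$end],     # sp$end is half-open in token coordinates
        type = sp$type,
        surface = substring(txt, tok$start[sp$start + 1L] + 1L, tok$end[sp$end]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) {
    res <- do.call(rbind, unname(out)); rownames(res) <- NULL; res
  } else {
    data.frame(section = character(0), start = integer(0), end = integer(0),
               type = character(0), surface = character(0), stringsAsFactors = FALSE)
  }
}

#' Span-level precision, recall and F1
#'
#' Exact-match scoring on (section, start, end, type).
#'
#' @param gold,pred span data.frames with those columns.
#' @return list with `precision`, `recall`, `f1` and the match counts.
#' @export
spanF1 <- function(gold, pred) {
  key <- function(sp) {
    if (nrow(sp) == 0L) return(character(0))
    paste(sp$section, sp$start, sp$end, sp$type, sep = "|")
  }
  g <- key(gold); p <- key(pred)
  tp <- length(intersect(g, p))
  prec <- if (length(p)) tp / length(p) else 0
  rec <- if (length(g)) tp / length(g) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       tp = tp, nGold = length(g), nPred = length(p))
}

#' Evaluate a NER model on annotated notes
#' @param model a `tcmNerModel`.
#' @param notes annotated `tcmNote` list.
#' @return micro-averaged list as in [spanF1()].
#' @export
nerEvaluate <- function(model, notes) {
  tp <- 0L; nG <- 0L; nP <- 0L
  for (note in notes) {
    pred <- nerPredict(model, note)
    gold <- note$spans
    s <- spanF1(gold, pred)
    tp <- tp + s$tp; nG <- nG + s$nGold; nP <- nP + s$nPred
  }
  prec <- if (nP) tp / nP else 0
  rec <- if (nG) tp / nG else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp, nGold = nG, nPred = nP)
}

#' Assemble a structured record from a note's entity spans
#'
#' Entities are grouped by section; each duration entity is paired with its
#' nearest preceding symptom in the same section (a duration with no
#' preceding symptom is left unpaired and logged). Surfaces are standardized
#' against the lexicon; durations are parsed to days via the unit table
#' (day = 1, month = 30, year = 365).
#'
#' @param note a `tcmNote`.
#' @param spans span data.frame (`section`, `start`, `end`, `type`, and
#'   either `surface` or a `canonical` column); defaults to the note's gold
#'   spans.
#' @param lexicon a `tcmLexicon` for surface standardization; `NULL` keeps
#'   surfaces verbatim.
#' @return a `tcmRecord`: data.frame with `section`, `type`, `canonical`,
#'   `duration` (surface form or `NA`) and `durationDays`.
#' @export
structureRecord <- function(note, spans = note$spans, lexicon = NULL) {
  if (nrow(spans) == 0L) {
    return(structure(data.frame(section = character(0), type = character(0),
                                canonical = character(0), duration = character(0),
                                durationDays = numeric(0), stringsAsFactors = FALSE),
                     class = c("tcmRecord", "data.frame")))
  }
  if (is.null(spans$surface)) {
    spans$surface <- vapply(seq_len(nrow(spans)), function(i) {
      txt <- normalizeWidth(note$sections[[spans$section[i]]])
      substring(txt, spans$start[i] + 1L, spans$end[i])
    }, "")
  }
  spans$surface <- normalizeWidth(spans$surface)
  spans$canonicalTerm <- standardizeTerm(spans$surface, lexicon)
  rows <- list()
  for (nm in unique(spans$section)) {
    sp <- spans[spans$section == nm, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    lastSymptomRow <- NA_integer_
    for (i in seq_len(nrow(sp))) {
      if (sp$type[i] == "duration") {
        if (is.na(lastSymptomRow)) {
          tcmLog("unpaired duration '%s' in section %s of %s",
                 sp$surface[i], nm, note$note_id)
        } else {
          rows[[lastSymptomRow]]$duration <- sp$canonicalTerm[i]
          rows[[lastSymptomRow]]$durationDays <- parseDuration(sp$canonicalTerm[i])
        }
      } else {
        rows[[length(rows) + 1L]] <- list(section = nm, type = sp$type[i],
                                          canonical = sp$canonicalTerm[i],
                                          duration = NA_character_,
                                          durationDays = NA_real_)
        if (sp$type[i] == "symptom") lastSymptomRow <- length(rows)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(df, class = c("tcmRecord", "data.frame"))
}

#' Parse a duration surface form to days
#'
#' Recognizes `<n>-days`, `<n>-months`, `<n>-years`; unit conversion
#' day = 1, month = 30, year = 365. Unparseable input returns `NA`.
#' @param x character vector.
#' @return numeric vector of days.
#' @export
parseDuration <- function(x) {
  nx <- normalizeWidth(x)
  m <- regexec("^([0-9]+)-(days|months|years)$", nx)
  res <- regmatches(nx, m)
  vapply(res, function(r) {
    if (length(r) != 3L) return(NA_real_)
    as.numeric(r[2]) * c(days = 1, months = 30, years = 365)[[r[3]]]
  }, 0)
}
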