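#' Base learner specifications for the integrated model
#'
#' The four heterogeneous base learners of the per-disease integrated model:
#' a back-propagation multilayer perceptron, a support vector classifier, a
#' random forest, and extreme gradient boosting.
#'
#' @return named list of specs, each with `kind` and `hyper`.
#' @export
baseLearnerSpecs <- function() {
  list(
    bp = list(kind = "backprop-mlp", hyper = list(size = 4L, decay = 1e-3, maxit = 100L)),
    svc = list(kind = "support-vector-classifier", hyper = list(cost = 10, kernel = "radial")),
    rf = list(kind = "random-forest", hyper = list(ntree = 200L)),
    xgb = list(kind = "extreme-gradient-boosting",
               hyper = list(nrounds = 60L, max_depth = 4L, eta = 0.3))
  )
}

# small default hyperparameter grids for the optional resampled search
defaultBaseGrids <- function() {
  list(
    bp = list(list(size = 2L, decay = 1e-3, maxit = 100L),
              list(size = 4L, decay = 1e-3, maxit = 100L)),
    svc = list(list(cost = 1, kernel = "radial"), list(cost = 10, kernel = "radial")),
    rf = list(list(ntree = 100L), list(ntree = 200L)),
    xgb = list(list(nrounds = 30L, max_depth = 3L, eta = 0.3),
               list(nrounds = 60L, max_depth = 4L, eta = 0.3))
  )
}

# fit one base learner; returns an object predictBase() understands.
# A single-class y yields a constant predictor regardless of kind.
# Zero-variance columns (features never observed for this disease's records)
# are dropped before fitting; the kept-column set travels with the model.
fitBase <- function(key, x, y, classes, hyper, seed) {
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    return(structure(list(key = key, constant = unique(y), classes = classes),
                     class = "tcmBaseLearner"))
  }
  keep <- which(apply(x, 2L, function(v) any(v != v[1L])))
  if (length(keep) == 0L) keep <- 1L
  x <- x[, keep, drop = FALSE]
  present <- sort(unique(y))
  fit <- withSeed(seed, switch(
    key,
    bp = nnet::nnet(x = x, y = nnet::class.ind(factor(y, levels = present)),
                    size = hyper$size, decay = hyper$decay, maxit = hyper$maxit,
                    softmax = TRUE, trace = FALSE, MaxNWts = 1e6),
    svc = e1071::svm(x = x, y = factor(y, levels = present), kernel = hyper$kernel,
                     cost = hyper$cost, probability = TRUE, scale = FALSE),
    rf = randomForest::randomForest(x = x, y = factor(y, levels = present),
                                    ntree = hyper$ntree),
    xgb = xgboost::xgboost(
      x = x, y = factor(y, levels = present),
      nrounds = hyper$nrounds, max_depth = hyper$max_depth,
      learning_rate = hyper$eta, nthreads = 1L, verbosity = 0, seed = seed %% 2147483647L
    ),
    stop("unknown base learner: ", key, call. = FALSE)
  ))
  structure(list(key = key, fit = fit, present = present, classes = classes,
                 keep = keep),
            class = "tcmBaseLearner")
}

# class-probability matrix (n x |classes|) and predicted labels
predictBase <- function(obj, x) {
  classes <- obj$classes
  n <- nrow(x)
  if (!is.null(obj$constant)) {
    P <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
    P[, obj$constant] <- 1
  } else {
    x <- x[, obj$keep, drop = FALSE]
    present <- obj$present
    Pp <- switch(
      obj$key,
      bp = {
        p <- stats::predict(obj$fit, x)
        if (is.null(dim(p))) p <- matrix(p, ncol = length(present))
        colnames(p) <- present
        p
      },
      svc = {
        pr <- stats::predict(obj$fit, x, probability = TRUE)
        attr(pr, "probabilities")[, present, drop = FALSE]
      },
      rf = stats::predict(obj$fit, x, type = "prob")[, present, drop = FALSE],
      xgb = {
        p <- stats::predict(obj$fit, x, type = "response")
        if (is.null(dim(p))) {
          # binary fit: response is the probability of the second level
          p <- cbind(1 - p, p)
          colnames(p) <- present
        }
        p[, present, drop = FALSE]
      }
    )
    P <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
    P[, present] <- as.matrix(Pp)
  }
  labels <- classes[max.col(P, ties.method = "first")]
  list(labels = labels, probs = P,
       confidence = P[cbind(seq_len(n), match(labels, classes))])
}

# k-fold + bootstrap resampled accuracy of one hyperparameter setting
resampledAccuracy <- function(key, x, y, hyper, folds, seed) {
  withSeed(seed, {
    fold <- stratifiedFolds(y, folds)
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      boot <- tr[sample.int(length(tr), length(tr), replace = TRUE)]
      if (length(unique(y[boot])) < 2L) boot <- tr
      m <- fitBase(key, x[boot, , drop = FALSE], y[boot], sort(unique(y)), hyper,
                   seed + f)
      acc[f] <- mean(predictBase(m, x[te, , drop = FALSE])$labels == y[te])
    }
    mean(acc)
  })
}

stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

#' Fit the integrated syndrome model for one disease
#'
#' Fits the four base learners on the same class-balanced training records of
#' the disease's notes. With `tune = TRUE` each learner's hyperparameters are
#' first selected from a small grid by k-fold cross-validation with bootstrap
#' resampling of the training part. A disease with a single observed syndrome
#' yields a degenerate model that always returns that syndrome (logged).
#'
#' @param disease disease id.
#' @param x numeric feature matrix for the disease's notes.
#' @param y gold syndrome per row.
#' @param seed integer seed.
#' @param specs base learner specs ([baseLearnerSpecs()]).
#' @param balance balance syndrome classes to the majority size before
#'   fitting.
#' @param tune run the small resampled hyperparameter search.
#' @param tuneFolds folds for the search.
#' @return a `tcmIntegratedModel`.
#' @export
fitIntegrated <- function(disease, x, y, seed = 1L, specs = baseLearnerSpecs(),
                          balance = TRUE, tune = FALSE, tuneFolds = 3L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) == 1L) {
    tcmLog("disease %s has a single syndrome (%s); constant predictor", disease,
           classes)
    return(structure(list(disease = disease, classes = classes, degenerate = TRUE,
                          learners = NULL),
                     class = "tcmIntegratedModel"))
  }
  tab <- table(y)
  if (any(tab < 2L)) {
    stop(sprintf("disease %s: syndrome(s) with < 2 records: %s", disease,
                 paste(names(tab)[tab < 2L], collapse = ", ")), call. = FALSE)
  }
  if (balance) {
    bal <- balanceClasses(x, y, max(tab), seed = seed)
    x <- bal$x; y <- bal$labels
  }
  learners <- list()
  i <- 0L
  for (key in names(specs)) {
    i <- i + 1L
    hyper <- specs[[key]]$hyper
    if (tune) {
      grid <- defaultBaseGrids()[[key]]
      accs <- vapply(seq_along(grid), function(g) {
        resampledAccuracy(key, x, y, grid[[g]], tuneFolds, seed + 100L * i + g)
      }, 0)
      hyper <- grid[[which.max(accs)]]
    }
    learners[[key]] <- fitBase(key, x, y, classes, hyper, seed + i)
  }
  structure(list(disease = disease, classes = classes, degenerate = FALSE,
                 learners = learners),
            class = "tcmIntegratedModel")
}

#' @export
print.tcmIntegratedModel <- function(x, ...) {
  cat(sprintf("tcmIntegratedModel[%s]: %d syndromes%s\n", x$disease,
              length(x$classes),
              if (isTRUE(x$degenerate)) " (degenerate constant predictor)" else
                sprintf(", learners: %s", paste(names(x$learners), collapse = ", "))))
  invisible(x)
}

#' Majority-rule vote over the four base learners
#'
#' The plurality label wins. Ties among the top vote counts are broken by the
#' highest mean confidence over the tied label's voters; residual ties fall
#' back to lexicographic label order.
#'
#' @param labels character vector of predicted labels (one per learner).
#' @param confidences the learners' predicted-class probabilities.
#' @return the winning label.
#' @export
#' @examples
#' majorityVote(c("A", "A", "B", "B"), c(0.9, 0.9, 0.6, 0.6)) # "A"
majorityVote <- function(labels, confidences) {
  stopifnot(length(labels) == length(confidences))
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  meanConf <- vapply(top, function(l) mean(confidences[labels == l]), 0)
  best <- top[meanConf == max(meanConf)]
  sort(best)[1L]
}

# ranked labels: vote count desc, mean voter confidence desc, label asc
rankVotes <- function(labels, confidences, classes) {
  votes <- vapply(classes, function(l) sum(labels == l), 0L)
  meanConf <- vapply(classes, function(l) {
    if (any(labels == l)) mean(confidences[labels == l]) else 0
  }, 0)
  ord <- order(-votes, -meanConf, classes)
  data.frame(syndrome = classes[ord], votes = votes[ord],
             meanConfidence = meanConf[ord], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Predict a ranked syndrome list for one note
#'
#' Looks up the disease's integrated model in the registry and ranks its
#' syndromes by (vote count, mean voter confidence, label); the top entry
#' equals [majorityVote()] over the four learners.
#'
#' @param features numeric feature vector (or 1-row matrix).
#' @param disease disease id used to select the model.
#' @param registry a `tcmRegistry` from [buildRegistry()].
#' @return data.frame `syndrome`, `votes`, `meanConfidence` in rank order.
#' @export
predictSyndrome <- function(features, disease, registry) {
  model <- registry$models[[disease]]
  if (is.null(model)) stop("no model for disease ", disease, call. = FALSE)
  if (is.null(dim(features))) features <- matrix(features, 1L)
  if (isTRUE(model$degenerate)) {
    return(data.frame(syndrome = model$classes, votes = 4L, meanConfidence = 1,
                      stringsAsFactors = FALSE))
  }
  labels <- character(0); confs <- numeric(0)
  for (key in names(model$learners)) {
    pr <- predictBase(model$learners[[key]], features)
    labels <- c(labels, pr$labels[1L]); confs <- c(confs, pr$confidence[1L])
  }
  rankVotes(labels, confs, model$classes)
}

#' Fit one integrated model per disease
#'
#' @param xByDisease named list: disease -> feature matrix.
#' @param yByDisease named list: disease -> syndrome labels.
#' @param seed integer seed.
#' @param ... passed to [fitIntegrated()].
#' @return a `tcmRegistry` (named list of `tcmIntegratedModel`).
#' @export
buildRegistry <- function(xByDisease, yByDisease, seed = 1L, ...) {
  stopifnot(identical(names(xByDisease), names(yByDisease)))
  models <- list()
  i <- 0L
  for (d in names(xByDisease)) {
    i <- i + 1L
    models[[d]] <- fitIntegrated(d, xByDisease[[d]], yByDisease[[d]],
                                 seed = seed + 1000L * i, ...)
  }
  structure(list(models = models, diseases = names(models)), class = "tcmRegistry")
}

#' @export
print.tcmRegistry <- function(x, ...) {
  cat(sprintf("tcmRegistry: %d per-disease integrated models\n", length(x$models)))
  invisible(x)
}

#' Cross-validated accuracies of the base learners and the integrated vote
#'
#' Stratified k-fold cross-validation on one disease's records: in each fold
#' the four base learners are fitted on the training part and scored on the
#' held-out part, and the integrated prediction is the majority vote of the
#' four. Classes with fewer records than `folds` reduce the fold count (with
#' a warning); a single-syndrome input trivially scores 1 everywhere.
#'
#' @param x feature matrix of one disease's records.
#' @param y syndrome labels.
#' @param folds requested folds (default 5).
#' @param seed integer seed.
#' @param specs base learner specs.
#' @return named numeric vector: `bp`, `svc`, `rf`, `xgb`, `integrated`.
#' @export
evaluateModels <- function(x, y, folds = 5L, seed = 1L, specs = baseLearnerSpecs()) {
  y <- as.character(y)
  kinds <- names(specs)
  if (length(unique(y)) == 1L) {
    return(stats::setNames(rep(1, length(kinds) + 1L), c(kinds, "integrated")))
  }
  minClass <- min(table(y))
  if (minClass < folds) {
    warning(sprintf("smallest syndrome has %d records; reducing folds from %d to %d",
                    minClass, folds, max(2L, minClass)))
    folds <- max(2L, minClass)
  }
  withSeed(seed, {
    fold <- stratifiedFolds(y, folds)
    correct <- matrix(0, 0, length(kinds) + 1L)
    classes <- sort(unique(y))
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      preds <- list(); confs <- list()
      for (i in seq_along(kinds)) {
        key <- kinds[i]
        m <- fitBase(key, x[tr, , drop = FALSE], y[tr], classes,
                     specs[[key]]$hyper, seed + 10L * f + i)
        pr <- predictBase(m, x[te, , drop = FALSE])
        preds[[key]] <- pr$labels; confs[[key]] <- pr$confidence
      }
      integ <- vapply(seq_along(te), function(j) {
        majorityVote(vapply(kinds, function(k) preds[[k]][j], ""),
                     vapply(kinds, function(k) confs[[k]][j], 0))
      }, "")
      ok <- cbind(matrix(unlist(lapply(kinds, function(k) preds[[k]] == y[te])),
                         ncol = length(kinds), dimnames = list(NULL, kinds)),
                  integrated = integ == y[te])
      correct <- rbind(correct, ok)
    }
    stats::setNames(colMeans(correct), c(kinds, "integrated"))
  })
}

#' Save / load a model registry
#'
#' One archive per disease plus a JSON manifest in a directory.
#' @param registry a `tcmRegistry`.
#' @param dir directory path (created if needed).
#' @return `saveRegistry` returns `dir` invisibly; `loadRegistry` a
#'   `tcmRegistry`.
#' @export
saveRegistry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(registry$models)) {
    saveRDS(registry$models[[d]], file.path(dir, paste0(d, ".rds")))
  }
  jsonlite::write_json(list(diseases = registry$diseases),
                       file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname saveRegistry
#' @export
loadRegistry <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  models <- lapply(man$diseases, function(d) readRDS(file.path(dir, paste0(d, ".rds"))))
  names(models) <- man$diseases
  structure(list(models = models, diseases = as.character(man$diseases)),
            class = "tcmRegistry")
}
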