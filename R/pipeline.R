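#' Top-k accuracy of ranked predictions
#'
#' Fraction of cases whose gold label appears among the first `k` ranked
#' predictions; non-decreasing in `k`.
#'
#' @param ranked list of character vectors, each in rank order.
#' @param gold gold label per case.
#' @param k ranked prefix length (>= 1).
#' @return a proportion in [0, 1].
#' @export
topkAccuracy <- function(ranked, gold, k) {
  stopifnot(k >= 1L, length(ranked) == length(gold))
  if (length(ranked) == 0L) stop("empty evaluation set", call. = FALSE)
  mean(vapply(seq_along(ranked), function(i) {
    gold[i] %in% utils::head(ranked[[i]], k)
  }, NA))
}

#' System-level (joint) top-k accuracy
#'
#' A case counts as correct iff the gold disease appears in the top-k disease
#' ranking AND the syndrome predicted by the gold disease's model equals the
#' gold syndrome. The gold disease's model is consulted only when the gold
#' disease is inside the top-k, which makes system top-k <= disease top-k by
#' construction.
#'
#' @param diseaseRanked list of ranked disease vectors.
#' @param syndromeTop predicted (top-1) syndrome per case, from the gold
#'   disease's model.
#' @param goldDisease,goldSyndrome gold labels per case.
#' @param k ranked prefix length.
#' @return a proportion in [0, 1].
#' @export
systemAccuracy <- function(diseaseRanked, syndromeTop, goldDisease, goldSyndrome, k) {
  stopifnot(length(diseaseRanked) == length(goldDisease),
            length(syndromeTop) == length(goldDisease))
  if (length(diseaseRanked) == 0L) return(0)
  mean(vapply(seq_along(diseaseRanked), function(i) {
    goldDisease[i] %in% utils::head(diseaseRanked[[i]], k) &&
      !is.na(syndromeTop[i]) && syndromeTop[i] == goldSyndrome[i]
  }, NA))
}

#' Desk-scale pipeline configuration
#'
#' Collects the component configurations and seeds for one training run. The
#' classifier defaults here are sized for synthetic corpora (short entity
#' token sequences); [textCnnConfig()] alone carries the published full-scale
#' geometry.
#'
#' @param seed master seed; component seeds derive from it.
#' @param nerCfg a [nerConfig()].
#' @param cnnL,cnnD,cnnFilters,cnnEpochs,cnnLr classifier settings.
#' @param scheme a [timeWeightScheme()].
#' @param tau feature-selection threshold.
#' @param kList ranked-list sizes reported.
#' @return a `tcmPipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           nerCfg = nerConfig(epochs = 6L, maxSequences = 4000L,
                                              seed = seed + 1L),
                           cnnL = 24L, cnnD = 48L, cnnFilters = 64L,
                           cnnEpochs = 15L, cnnLr = 0.01,
                           scheme = timeWeightScheme(), tau = 0,
                           kList = c(1L, 3L, 5L)) {
  structure(list(seed = as.integer(seed), nerCfg = nerCfg, cnnL = as.integer(cnnL),
                 cnnD = as.integer(cnnD), cnnFilters = as.integer(cnnFilters),
                 cnnEpochs = as.integer(cnnEpochs), cnnLr = cnnLr,
                 scheme = scheme, tau = tau, kList = as.integer(kList)),
            class = "tcmPipelineConfig")
}

# gold-annotation records for a set of notes
goldRecords <- function(notes, lexicon) {
  lapply(notes, function(n) structureRecord(n, spans = n$spans, lexicon = lexicon))
}

#' Train the disease-classification stage
#'
#' Builds the frozen feature index from the training records, derives entity
#' token sequences, and fits the text-convolution classifier.
#'
#' @param trainNotes,valNotes annotated `tcmNote` lists.
#' @param lexicon a `tcmLexicon`.
#' @param config a [pipelineConfig()].
#' @return list with `index`, `scheme`, `tau`, `cnn`, `classes`.
#' @export
trainDiseaseStage <- function(trainNotes, valNotes, lexicon, config) {
  recs <- goldRecords(trainNotes, lexicon)
  index <- buildFeatureIndex(recs)
  classes <- sort(unique(vapply(trainNotes, `[[`, "", "disease")))
  cnnCfg <- textCnnConfig(nClasses = length(classes), L = config$cnnL,
                          d = config$cnnD, nFilters = config$cnnFilters,
                          epochs = config$cnnEpochs, lr = config$cnnLr,
                          seed = config$seed + 2L)
  cnn <- cnnFit(lapply(recs, entityTokens),
                vapply(trainNotes, `[[`, "", "disease"),
                lapply(goldRecords(valNotes, lexicon), entityTokens),
                vapply(valNotes, `[[`, "", "disease"),
                cnnCfg, classes = classes)
  list(index = index, scheme = config$scheme, tau = config$tau, cnn = cnn,
       classes = classes)
}

#' Train the per-disease syndrome ensembles
#'
#' @param trainNotes annotated `tcmNote` list.
#' @param lexicon a `tcmLexicon`.
#' @param diseaseStage output of [trainDiseaseStage()] (for the feature index).
#' @param seed integer seed.
#' @param ... passed to [fitIntegrated()].
#' @return a `tcmRegistry`.
#' @export
trainSyndromeStage <- function(trainNotes, lexicon, diseaseStage, seed = 1L, ...) {
  recs <- goldRecords(trainNotes, lexicon)
  X <- vectorizeRecords(recs, diseaseStage$index, diseaseStage$scheme,
                        diseaseStage$tau)
  dis <- vapply(trainNotes, `[[`, "", "disease")
  syn <- vapply(trainNotes, `[[`, "", "syndrome")
  xByD <- lapply(split(seq_along(trainNotes), dis), function(ix) X[ix, , drop = FALSE])
  yByD <- split(syn, dis)
  buildRegistry(xByD, yByD, seed = seed, ...)
}

#' Train every stage of the pipeline on an annotated corpus
#'
#' Applies non-text stripping and the QC filter, makes a stratified 8:1:1
#' split, then trains the NER model, the disease classifier (with its frozen
#' feature index) and the per-disease syndrome registry on the training and
#' validation folds.
#'
#' @param notes list of annotated `tcmNote`.
#' @param lexicon the `tcmLexicon` used for standardization.
#' @param config a [pipelineConfig()].
#' @return a `tcmModels` bundle: `ner`, `disease` (see
#'   [trainDiseaseStage()]), `registry`, `lexicon`, `split`, `qc`.
#' @export
trainPipeline <- function(notes, lexicon, config = pipelineConfig()) {
  notes <- lapply(notes, stripNontext)
  qc <- qcFilter(notes)
  ids <- vapply(notes, `[[`, "", "note_id")
  keep <- notes[ids %in% qc$kept]
  dis <- vapply(keep, `[[`, "", "disease")
  split3 <- partitionCorpus(vapply(keep, `[[`, "", "note_id"), strata = dis,
                            seed = config$seed)
  pick <- function(idset) keep[vapply(keep, `[[`, "", "note_id") %in% idset]
  trainNotes <- pick(split3$train); valNotes <- pick(split3$val)
  ner <- nerFit(trainNotes, valNotes, config$nerCfg)
  disease <- trainDiseaseStage(trainNotes, valNotes, lexicon, config)
  registry <- trainSyndromeStage(trainNotes, lexicon, disease,
                                 seed = config$seed + 3L)
  structure(list(ner = ner, disease = disease, registry = registry,
                 lexicon = lexicon, split = split3, qc = qc, config = config),
            class = "tcmModels")
}

#' @export
print.tcmModels <- function(x, ...) {
  cat(sprintf("tcmModels: NER + %d-class disease classifier + %d syndrome models\n",
              length(x$disease$classes), length(x$registry$models)))
  invisible(x)
}

#' Run the full diagnostic pipeline on raw notes
#'
#' For every note: strip non-text, extract entities with the NER model, build
#' the structured record and feature vector, rank diseases with the
#' text-convolution classifier, and predict the syndrome with the integrated
#' model of the top-ranked disease. When gold labels are present an
#' evaluation report (disease, syndrome and joint system accuracies at each
#' k) is attached; its invariants (top-5 >= top-3 >= top-1, system <=
#' disease) hold on every corpus. With a `runDir`, predictions and the report
#' are written as JSONL/JSON.
#'
#' @param notes list of `tcmNote` (gold spans are ignored at inference).
#' @param models a `tcmModels` bundle from [trainPipeline()].
#' @param kList ranked-list sizes.
#' @param runDir optional output directory.
#' @return list with `predictions` (data.frame) and `report`
#'   (a `tcmEvalReport` or `NULL` when no gold labels).
#' @export
runPipeline <- function(notes, models, kList = c(1L, 3L, 5L), runDir = NULL) {
  kMax <- max(kList, 1L)
  n <- length(notes)
  ranked <- vector("list", n)
  synPredicted <- rep(NA_character_, n)   # via the predicted top-1 disease
  synViaGold <- rep(NA_character_, n)     # via the gold disease's model
  goldD <- rep(NA_character_, n); goldS <- rep(NA_character_, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    note <- stripNontext(notes[[i]])
    ids[i] <- note$note_id
    spans <- nerPredict(models$ner, note)
    rec <- structureRecord(note, spans = spans, lexicon = models$lexicon)
    feats <- vectorizeRecord(rec, models$disease$index, models$disease$scheme,
                             models$disease$tau)
    top <- predictTopk(models$disease$cnn, entityTokens(rec), k = kMax)
    ranked[[i]] <- top$disease
    d1 <- top$disease[1L]
    if (d1 %in% names(models$registry$models)) {
      synPredicted[i] <- predictSyndrome(feats, d1, models$registry)$syndrome[1L]
    }
    if (!is.null(notes[[i]]$disease)) {
      goldD[i] <- notes[[i]]$disease
      goldS[i] <- notes[[i]]$syndrome
      if (goldD[i] %in% names(models$registry$models)) {
        synViaGold[i] <- predictSyndrome(feats, goldD[i],
                                         models$registry)$syndrome[1L]
      }
    }
  }
  predictions <- data.frame(
    note_id = ids,
    disease_top = vapply(ranked, function(r) if (length(r)) r[1L] else NA_character_, ""),
    disease_ranked = vapply(ranked, paste, "", collapse = ";"),
    syndrome_top = synPredicted,
    stringsAsFactors = FALSE
  )
  report <- NULL
  if (n > 0L && !anyNA(goldD)) {
    diseaseTopk <- stats::setNames(
      vapply(kList, function(k) topkAccuracy(ranked, goldD, k), 0),
      paste0("top", kList))
    systemTopk <- stats::setNames(
      vapply(kList, function(k) {
        systemAccuracy(ranked, synViaGold, goldD, goldS, k)
      }, 0), paste0("top", kList))
    perDisease <- do.call(rbind, lapply(sort(unique(goldD)), function(d) {
      ix <- which(goldD == d)
      data.frame(disease = d, n = length(ix),
                 syndromeAccuracy = mean(!is.na(synViaGold[ix]) &
                                           synViaGold[ix] == goldS[ix]),
                 stringsAsFactors = FALSE)
    }))
    report <- structure(list(diseaseTopk = diseaseTopk, systemTopk = systemTopk,
                             syndromePerDisease = perDisease, kList = kList),
                        class = "tcmEvalReport")
    checkEvalReport(report)
  }
  if (!is.null(runDir)) {
    dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(predictions, file.path(runDir, "predictions.csv"),
                     row.names = FALSE)
    if (!is.null(report)) {
      jsonlite::write_json(unclass(report), file.path(runDir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(predictions = predictions, report = report)
}

# report invariants: proportions in [0,1], monotone in k, system <= disease
checkEvalReport <- function(report) {
  v <- c(report$diseaseTopk, report$systemTopk, report$syndromePerDisease$syndromeAccuracy)
  stopifnot(all(v >= 0 & v <= 1))
  stopifnot(!is.unsorted(report$diseaseTopk), !is.unsorted(report$systemTopk))
  stopifnot(all(report$systemTopk <= report$diseaseTopk + 1e-12))
  invisible(report)
}

#' @export
print.tcmEvalReport <- function(x, ...) {
  cat("tcmEvalReport\n  disease accuracy: ",
      paste(sprintf("%s=%.3f", names(x$diseaseTopk), x$diseaseTopk), collapse = "  "),
      "\n  system accuracy:  ",
      paste(sprintf("%s=%.3f", names(x$systemTopk), x$systemTopk), collapse = "  "),
      "\n  mean per-disease syndrome accuracy: ",
      sprintf("%.3f", mean(x$syndromePerDisease$syndromeAccuracy)), "\n", sep = "")
  invisible(x)
}
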