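#' Predefined EHR note sections
#'
#' The ordered section inventory of an admission note: chief complaint,
#' history of present illness, medical and family history, physical exam,
#' tongue and pulse observations, and the structured admission and discharge
#' pages.
#' @export
tcmSections <- function() {
  c("chief_complaint", "present_illness", "medical_history", "family_history",
    "physical_exam", "tongue", "pulse", "admission", "discharge")
}

#' Quality-control violation kinds
#' @export
tcmQcKinds <- function() c("missing_page", "inconsistent", "nonstandard_complaint")

#' Generator configuration for a synthetic annotated corpus
#'
#' @param ontology a `tcmOntology`.
#' @param perClassCounts named integer vector, disease -> number of notes.
#' @param qcViolations named integer vector over [tcmQcKinds()]: how many notes
#'   to plant each violation in. Violations are planted in distinct notes.
#' @param seed integer; the corpus is byte-reproducible given the config.
#' @param lexicon a `tcmLexicon`; defaults to `makeLexicon(ontology)`.
#' @param maxNoteTokens soft cap on tokens per note; bounds the filler draws.
#' @param noiseProb probability that a symptom slot is filled from the global
#'   symptom pool instead of the note's disease/syndrome markers. At 0, notes
#'   of different diseases use disjoint symptom lexica.
#' @param synonymProb probability a term is realized as a synonym surface form.
#' @param fullWidthProb probability a token is rendered in full-width
#'   characters (simulating mixed-width clinical text).
#' @param nonTextProb probability a non-text placeholder token (for example an
#'   embedded image) is inserted into the physical-exam section.
#' @return an object of class `tcmGenConfig`.
#' @export
genConfig <- function(ontology, perClassCounts, qcViolations = integer(0),
                      seed = 1L, lexicon = makeLexicon(ontology),
                      maxNoteTokens = 60L, noiseProb = 0,
                      synonymProb = 0.2, fullWidthProb = 0.1,
                      nonTextProb = 0) {
  validateOntology(ontology)
  if (length(perClassCounts) == 0L || is.null(names(perClassCounts)) ||
      !all(names(perClassCounts) %in% ontology$diseases)) {
    stop("perClassCounts must be a named vector over ontology diseases", call. = FALSE)
  }
  if (any(perClassCounts < 0)) stop("note counts must be >= 0", call. = FALSE)
  if (length(qcViolations)) {
    if (!all(names(qcViolations) %in% tcmQcKinds())) {
      stop("unknown QC violation kind: ",
           paste(setdiff(names(qcViolations), tcmQcKinds()), collapse = ", "),
           call. = FALSE)
    }
    if (sum(qcViolations) > sum(perClassCounts)) {
      stop("total QC violations exceed the total note count", call. = FALSE)
    }
  }
  structure(
    list(ontology = ontology, perClassCounts = perClassCounts,
         qcViolations = qcViolations, seed = as.integer(seed),
         lexicon = lexicon, maxNoteTokens = as.integer(maxNoteTokens),
         noiseProb = noiseProb, synonymProb = synonymProb,
         fullWidthProb = fullWidthProb, nonTextProb = nonTextProb),
    class = "tcmGenConfig"
  )
}

# ASCII 0x21-0x7E <-> full-width forms U+FF01-U+FF5E (offset 0xFEE0);
# the full-width space is U+3000
toFullWidth <- function(token) {
  cp <- utf8ToInt(token)
  asc <- cp >= 0x21L & cp <= 0x7EL
  cp[asc] <- cp[asc] + 0xFEE0L
  cp[cp == 0x20L] <- 0x3000L
  intToUtf8(cp)
}

#' Generate a seeded, fully annotated synthetic EHR corpus
#'
#' Each note carries sectioned text, gold entity spans (0-based, half-open
#' character offsets within a section), a gold disease and syndrome drawn from
#' the ontology, and QC flags for any planted violation. The chief complaint
#' follows the standard pattern of symptoms each qualified by a duration
#' ("sym 3-days ..."); durations also occur in the present-illness section.
#' The planted violations are exactly the three kinds the QC filter screens
#' for: a missing discharge page, admission/discharge field inconsistency, and
#' a non-standard chief complaint.
#'
#' @param config a `tcmGenConfig`.
#' @return a list of `tcmNote` objects.
#' @export
#' @examples
#' ont <- buildOntology(2, 3, 2, seed = 1)
#' notes <- generateCorpus(genConfig(ont, c(D01 = 3, D02 = 2), seed = 7))
#' length(notes)
generateCorpus <- function(config) {
  stopifnot(inherits(config, "tcmGenConfig"))
  lex <- config$lexicon
  ont <- config$ontology
  synByCanon <- split(names(lex$synonyms), lex$synonyms)
  tng <- typeTerms(lex, "tongue"); pls <- typeTerms(lex, "pulse")
  his <- typeTerms(lex, "history"); gsym <- allSymptoms(lex)
  fillerBudget <- max(0L, config$maxNoteTokens - 30L)

  withSeed(config$seed, {
    diseases <- rep(names(config$perClassCounts), times = config$perClassCounts)
    n <- length(diseases)
    notes <- vector("list", n)
    for (i in seq_len(n)) {
      d <- diseases[i]
      s <- ont$map[[d]][sample.int(length(ont$map[[d]]), 1L)]
      notes[[i]] <- buildNote(sprintf("note%05d", i), d, s, lex, synByCanon,
                              tng, pls, his, gsym, config, fillerBudget)
    }
    # plant QC violations in distinct notes
    if (length(config$qcViolations) && sum(config$qcViolations) > 0) {
      victims <- sample.int(n, sum(config$qcViolations))
      at <- 0L
      for (kind in names(config$qcViolations)) {
        k <- config$qcViolations[[kind]]
        if (k > 0) {
          idx <- victims[(at + 1L):(at + k)]
          for (j in idx) notes[[j]] <- plantViolation(notes[[j]], kind, lex)
          at <- at + k
        }
      }
    }
    notes
  })
}

drawDuration <- function() {
  u <- sample(c("days", "days", "days", "days", "months", "years"), 1L)
  nmax <- switch(u, days = 9L, months = 11L, years = 3L)
  sprintf("%d-%s", sample.int(nmax, 1L), u)
}

pickSym <- function(intended, gsym, noiseProb) {
  if (noiseProb > 0 && stats::runif(1) < noiseProb) sample(gsym, 1L)
  else intended[sample.int(length(intended), 1L)]
}

# assemble one note: token/type/canonical triples per section, then realize
buildNote <- function(id, d, s, lex, synByCanon, tng, pls, his, gsym,
                      config, fillerBudget) {
  dsy <- diseaseSymptoms(lex, d); ssy <- syndromeSymptoms(lex, s)
  sec <- list()
  add <- function(tok, type = NA_character_, canon = NA_character_) {
    list(token = tok, type = type, canon = canon)
  }
  sym <- function(pool) {
    cn <- pickSym(pool, gsym, config$noiseProb)
    add(cn, "symptom", cn)
  }
  dur <- function() { t <- drawDuration(); add(t, "duration", t) }
  fill <- function() add(sample(lex$fillers, 1L))

  sec$chief_complaint <- list(sym(dsy), dur(), sym(ssy), dur())
  pi <- list(sym(dsy), sym(ssy))
  if (stats::runif(1) < 0.7) pi <- c(pi, list(dur()))
  pi <- c(pi, list(sym(if (stats::runif(1) < 0.5) dsy else ssy)))
  nf <- min(fillerBudget, 1L + stats::rbinom(1L, 2L, 0.5))
  for (k in seq_len(nf)) pi <- c(pi, list(fill()))
  sec$present_illness <- pi
  mh <- list(add(sample(his, 1L), "history", NA))
  mh[[1]]$canon <- mh[[1]]$token
  if (stats::runif(1) < 0.5) mh <- c(mh, list(sym(dsy)))
  sec$medical_history <- mh
  fh <- add(sample(his, 1L)); fh$type <- "history"; fh$canon <- fh$token
  sec$family_history <- list(fh)
  pe <- list(fill(), fill())
  if (config$nonTextProb > 0 && stats::runif(1) < config$nonTextProb) {
    pe <- append(pe, list(add("<img>")), after = 1L)
  }
  sec$physical_exam <- pe
  tt <- add(sample(tng, 1L), "tongue"); tt$canon <- tt$token
  sec$tongue <- list(tt)
  pp <- add(sample(pls, 1L), "pulse"); pp$canon <- pp$token
  sec$pulse <- list(pp)

  sex <- sample(c("M", "F"), 1L); age <- sample(18:90, 1L)
  page <- sprintf("disease=%s sex=%s age=%d", d, sex, age)

  sections <- list(); spans <- list()
  for (nm in names(sec)) {
    items <- sec[[nm]]
    toks <- vapply(items, `[[`, "", "token")
    types <- vapply(items, `[[`, "", "type")
    canon <- vapply(items, `[[`, "", "canon")
    # realize surfaces: synonym swap for lexicon terms, then width mixing
    for (j in seq_along(toks)) {
      if (!is.na(canon[j]) && canon[j] %in% names(synByCanon) &&
          stats::runif(1) < config$synonymProb) {
        forms <- synByCanon[[canon[j]]]
        toks[j] <- forms[sample.int(length(forms), 1L)]
      }
      if (config$fullWidthProb > 0 && stats::runif(1) < config$fullWidthProb) {
        toks[j] <- toFullWidth(toks[j])
      }
    }
    lens <- nchar(toks)
    starts <- c(0L, cumsum(lens + 1L)[-length(lens)])
    sections[[nm]] <- paste(toks, collapse = " ")
    ent <- !is.na(types)
    if (any(ent)) {
      spans[[nm]] <- data.frame(
        section = nm, start = starts[ent], end = (starts + lens)[ent],
        type = types[ent], canonical = canon[ent], stringsAsFactors = FALSE
      )
    }
  }
  sections$admission <- page
  sections$discharge <- page
  spans <- if (length(spans)) do.call(rbind, unname(spans)) else emptySpans()
  rownames(spans) <- NULL
  structure(
    list(note_id = id, sections = sections, spans = spans,
         disease = d, syndrome = s, qc_flags = character(0)),
    class = "tcmNote"
  )
}

emptySpans <- function() {
  data.frame(section = character(0), start = integer(0), end = integer(0),
             type = character(0), canonical = character(0),
             stringsAsFactors = FALSE)
}

plantViolation <- function(note, kind, lex) {
  if (kind == "missing_page") {
    note$sections$discharge <- NULL
  } else if (kind == "inconsistent") {
    pg <- note$sections$discharge
    age <- as.integer(sub(".*age=(\\d+).*", "\\1", pg))
    note$sections$discharge <- sub("age=\\d+", sprintf("age=%d", age + 1L), pg)
  } else if (kind == "nonstandard_complaint") {
    note$sections$chief_complaint <- paste(sample(lex$fillers, 2L), collapse = " ")
    note$spans <- note$spans[note$spans$section != "chief_complaint", , drop = FALSE]
    rownames(note$spans) <- NULL
  } else {
    stop("unknown QC violation kind: ", kind, call. = FALSE)
  }
  note$qc_flags <- sort(unique(c(note$qc_flags, kind)))
  note
}

#' @export
print.tcmNote <- function(x, ...) {
  cat(sprintf("tcmNote %s: disease=%s syndrome=%s, %d sections, %d spans%s\n",
              x$note_id, x$disease, x$syndrome, length(x$sections),
              nrow(x$spans),
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Render a note as raw freestyle text with bracketed section headers
#'
#' Inverse of [splitSections()]: sections are concatenated in order, each
#' preceded by a `[section_name]` marker line.
#' @param note a `tcmNote`.
#' @return a single string.
#' @export
renderNote <- function(note) {
  paste(vapply(names(note$sections), function(nm) {
    sprintf("[%s]\n%s", nm, note$sections[[nm]])
  }, ""), collapse = "\n")
}
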