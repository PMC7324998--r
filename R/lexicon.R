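#' Entity types recognized by the pipeline
#'
#' Minimal clinical inventory: symptoms, their durations, tongue-quality and
#' pulse observations, and medical-history items.
#' @export
tcmEntityTypes <- function() c("symptom", "duration", "tongue", "pulse", "history")

#' Build the synthetic entity lexicon for an ontology
#'
#' Constructs the surface-form inventory the corpus generator draws from and
#' the standardization dictionary the feature extractor uses. Symptom terms are
#' split into disease markers (terms used only by notes of one disease) and
#' syndrome markers (terms tied to one syndrome, shared across the diseases
#' that share the syndrome); this is what makes a zero-noise corpus separable
#' at both the disease and the syndrome level. Each canonical term also gets
#' synonym surface forms, emulating physicians wording the same finding
#' differently.
#'
#' @param ontology a `tcmOntology`.
#' @param symptomsPerDisease,symptomsPerSyndrome marker terms per class.
#' @param nTongue,nPulse,nHistory,nFillers sizes of the shared pools; fillers
#'   are non-entity tokens.
#' @param synonymsPerTerm synonym surfaces per canonical term.
#' @return an object of class `tcmLexicon` with elements `terms` (data.frame
#'   `canonical`, `type`, `disease`, `syndrome`), `synonyms` (named character
#'   vector, surface -> canonical, including the identity rows), `fillers`,
#'   and `durationUnits`.
#' @export
makeLexicon <- function(ontology,
                        symptomsPerDisease = 3L,
                        symptomsPerSyndrome = 3L,
                        nTongue = 6L, nPulse = 6L, nHistory = 8L,
                        nFillers = 20L, synonymsPerTerm = 2L) {
  validateOntology(ontology)
  dsym <- do.call(rbind, lapply(ontology$diseases, function(d) {
    data.frame(canonical = sprintf("sym_%s_%d", d, seq_len(symptomsPerDisease)),
               type = "symptom", disease = d, syndrome = NA_character_,
               stringsAsFactors = FALSE)
  }))
  ssym <- do.call(rbind, lapply(ontology$syndromes, function(s) {
    data.frame(canonical = sprintf("sym_%s_%d", s, seq_len(symptomsPerSyndrome)),
               type = "symptom", disease = NA_character_, syndrome = s,
               stringsAsFactors = FALSE)
  }))
  pool <- function(prefix, n, type) {
    data.frame(canonical = sprintf("%s_%02d", prefix, seq_len(n)), type = type,
               disease = NA_character_, syndrome = NA_character_,
               stringsAsFactors = FALSE)
  }
  terms <- rbind(dsym, ssym,
                 pool("tng", nTongue, "tongue"),
                 pool("pls", nPulse, "pulse"),
                 pool("his", nHistory, "history"))
  syn <- terms$canonical
  names(syn) <- terms$canonical
  if (synonymsPerTerm > 0L) {
    for (k in seq_len(synonymsPerTerm)) {
      extra <- terms$canonical
      names(extra) <- paste0(terms$canonical, "~", letters[k])
      syn <- c(syn, extra)
    }
  }
  structure(
    list(terms = terms,
         synonyms = syn,
         fillers = sprintf("fill_%02d", seq_len(nFillers)),
         durationUnits = c(days = 1L, months = 30L, years = 365L)),
    class = "tcmLexicon"
  )
}

#' @export
print.tcmLexicon <- function(x, ...) {
  cat(sprintf("tcmLexicon: %d canonical terms (%s), %d surface forms, %d fillers\n",
              nrow(x$terms),
              paste(sprintf("%d %s", table(x$terms$type)[unique(x$terms$type)],
                            unique(x$terms$type)), collapse = ", "),
              length(x$synonyms), length(x$fillers)))
  invisible(x)
}

# surface forms of one canonical term (identity + synonyms)
surfacesOf <- function(lexicon, canonical) {
  names(lexicon$synonyms)[lexicon$synonyms == canonical]
}

# symptom canonicals for a disease / syndrome / the global symptom pool
diseaseSymptoms <- function(lexicon, d) {
  lexicon$terms$canonical[lexicon$terms$type == "symptom" &
                            !is.na(lexicon$terms$disease) &
                            lexicon$terms$disease == d]
}
syndromeSymptoms <- function(lexicon, s) {
  lexicon$terms$canonical[lexicon$terms$type == "symptom" &
                            !is.na(lexicon$terms$syndrome) &
                            lexicon$terms$syndrome == s]
}
allSymptoms <- function(lexicon) {
  lexicon$terms$canonical[lexicon$terms$type == "symptom"]
}
typeTerms <- function(lexicon, type) {
  lexicon$terms$canonical[lexicon$terms$type == type]
}
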