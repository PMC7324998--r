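#' Standardize surface forms against the lexicon
#'
#' Physicians word the same finding differently; the predefined dictionary
#' maps every known surface form (synonym) to its canonical term. Unknown
#' surfaces are returned verbatim and logged. Canonical terms map to
#' themselves, so the operation is idempotent.
#'
#' @param term character vector of surface forms.
#' @param lexicon a `tcmLexicon`, or `NULL` to pass everything through.
#' @return character vector of canonical terms.
#' @export
standardizeTerm <- function(term, lexicon = NULL) {
  if (is.null(lexicon) || length(term) == 0L) return(term)
  hit <- lexicon$synonyms[term]
  unknown <- is.na(hit)
  if (any(unknown)) {
    miss <- unique(term[unknown])
    # durations and fillers are not dictionary terms; only log surprises
    surprising <- miss[!grepl(durationPattern(), miss) & !(miss %in% lexicon$fillers)]
    if (length(surprising)) {
      tcmLog("surface form(s) not in dictionary, kept verbatim: %s",
             paste(utils::head(surprising, 5L), collapse = ", "))
    }
    hit[unknown] <- term[unknown]
  }
  unname(hit)
}

#' Merge same-entity occurrences across sections
#'
#' The same named entity can be mentioned in several sections (chief
#' complaint, present illness, history...). Occurrences sharing a canonical
#' id are merged into one group that retains every (section, duration)
#' occurrence.
#'
#' @param record a `tcmRecord` from [structureRecord()].
#' @return named list: canonical term -> data.frame(`section`,
#'   `durationDays`).
#' @export
splitAndJoin <- function(record) {
  if (nrow(record) == 0L) return(list())
  occ <- data.frame(section = record$section, durationDays = record$durationDays,
                    stringsAsFactors = FALSE)
  split(occ, record$canonical)
}

#' Expand symptom/duration pairs into feature terms
#'
#' Each symptom yields its bare term; a symptom paired with a duration
#' additionally yields the compound term `symptom#duration`, so a chief
#' complaint with two dated symptoms yields four feature terms. Output
#' preserves input order, bare before compound.
#'
#' @param pairs data.frame with columns `symptom` and `duration` (surface
#'   form or `NA` for undated symptoms).
#' @return character vector of feature terms.
#' @export
#' @examples
#' expandSymptomTime(data.frame(symptom = c("coughing", "coughing_phlegm"),
#'                              duration = c("3-days", "2-days")))
expandSymptomTime <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(pairs))) {
    out <- c(out, pairs$symptom[i])
    if (!is.na(pairs$duration[i])) {
      out <- c(out, paste0(pairs$symptom[i], "#", pairs$duration[i]))
    }
  }
  out
}

#' Linear time-weight scheme
#'
#' Weights follow the recurrence `weight(n+1) = weight(n) + increment` with
#' `increment = 1/N` and `weight(0) = 0` over `N` total time units, i.e.
#' `weight(k) = k/N`. Recency is rewarded by evaluating the weight at
#' `N - distance`: an occurrence at distance 0 (now) gets weight 1, one N
#' units in the past gets weight 0.
#'
#' @param N total number of time units (days) in the window.
#' @return a `tcmTimeWeightScheme` with fields `N` and `increment`.
#' @export
timeWeightScheme <- function(N = 1095L) {
  stopifnot(N >= 1)
  structure(list(N = as.numeric(N), increment = 1 / as.numeric(N)),
            class = "tcmTimeWeightScheme")
}

#' Time weight of an occurrence `n` time units in the past
#'
#' @param n non-negative distance in time units, `0 <= n <= N`.
#' @param scheme a [timeWeightScheme()].
#' @return `weight(N - n) = (N - n)/N`: 1 at distance 0, 0 at distance N.
#' @export
timeWeight <- function(n, scheme = timeWeightScheme()) {
  if (any(n < 0 | n > scheme$N)) {
    stop(sprintf("time distance must lie in [0, N=%g]", scheme$N), call. = FALSE)
  }
  (scheme$N - n) / scheme$N
}

#' Weighted sum over a feature group's occurrences
#'
#' Sums the time weight over all occurrences of a feature; an occurrence
#' without a time stamp contributes weight 1 (it is treated as current).
#'
#' @param distances numeric vector of time distances in units; `NA` means
#'   undated.
#' @param scheme a [timeWeightScheme()].
#' @return a single non-negative numeric value.
#' @export
weightedSum <- function(distances, scheme = timeWeightScheme()) {
  if (length(distances) == 0L) return(0)
  sum(ifelse(is.na(distances), 1, timeWeight(ifelse(is.na(distances), 0, distances),
                                             scheme)))
}

# all feature terms (bare + compound) of a record with their occurrence
# distances; the unit of the compound term carries its own distance
termOccurrences <- function(record) {
  if (nrow(record) == 0L) return(list())
  terms <- character(0); sect <- character(0); dd <- numeric(0)
  for (i in seq_len(nrow(record))) {
    terms <- c(terms, record$canonical[i])
    sect <- c(sect, record$section[i])
    dd <- c(dd, record$durationDays[i])
    if (record$type[i] == "symptom" && !is.na(record$duration[i])) {
      terms <- c(terms, paste0(record$canonical[i], "#", record$duration[i]))
      sect <- c(sect, record$section[i])
      dd <- c(dd, record$durationDays[i])
    }
  }
  split(data.frame(section = sect, durationDays = dd, stringsAsFactors = FALSE), terms)
}

#' Build the feature index from training records
#'
#' The index is frozen on the training split; out-of-vocabulary terms seen
#' later are dropped (with a log entry) during vectorization.
#'
#' @param records list of `tcmRecord`.
#' @return named integer vector, feature term -> position.
#' @export
buildFeatureIndex <- function(records) {
  terms <- sort(unique(unlist(lapply(records, function(r) names(termOccurrences(r))),
                              use.names = FALSE)))
  stats::setNames(seq_along(terms), terms)
}

#' Threshold and vectorize weighted feature groups
#'
#' Features whose weighted sum exceeds `tau` keep the weighted sum as their
#' coordinate value; all other coordinates are 0. Terms absent from the
#' index are dropped with a log entry.
#'
#' @param sums named numeric vector: feature term -> weighted sum.
#' @param index named integer feature index from [buildFeatureIndex()].
#' @param tau selection threshold (default 0: keep every observed feature).
#' @return numeric vector of length `length(index)`.
#' @export
selectAndVectorize <- function(sums, index, tau = 0) {
  v <- numeric(length(index))
  names(v) <- names(index)
  if (length(sums) == 0L) return(v)
  known <- names(sums) %in% names(index)
  if (any(!known)) {
    tcmLog("%d out-of-vocabulary feature(s) dropped", sum(!known))
  }
  keep <- sums[known]
  keep <- keep[keep > tau]
  v[names(keep)] <- unname(keep)
  v
}

#' Vectorize one structured record
#'
#' Full feature chain: merge occurrences across sections, expand dated
#' symptoms into bare + compound terms, apply the time-decay weighted sum
#' per term (distances beyond the scheme window are clamped to N, i.e.
#' weight 0, with a log entry), then threshold against the frozen index.
#'
#' @param record a `tcmRecord`.
#' @param index feature index from [buildFeatureIndex()].
#' @param scheme a [timeWeightScheme()].
#' @param tau selection threshold.
#' @return numeric feature vector of length `length(index)`.
#' @export
vectorizeRecord <- function(record, index, scheme = timeWeightScheme(), tau = 0) {
  groups <- termOccurrences(record)
  sums <- vapply(groups, function(g) {
    d <- g$durationDays
    over <- !is.na(d) & d > scheme$N
    if (any(over)) {
      tcmLog("%d occurrence(s) older than the %g-unit window clamped", sum(over),
             scheme$N)
      d[over] <- scheme$N
    }
    weightedSum(d, scheme)
  }, 0)
  selectAndVectorize(sums, index, tau)
}

#' Vectorize many records into a feature matrix
#' @param records list of `tcmRecord`.
#' @inheritParams vectorizeRecord
#' @return numeric matrix, one row per record, columns = index terms.
#' @export
vectorizeRecords <- function(records, index, scheme = timeWeightScheme(), tau = 0) {
  m <- do.call(rbind, lapply(records, vectorizeRecord, index = index,
                             scheme = scheme, tau = tau))
  if (is.null(m)) m <- matrix(0, 0, length(index))
  colnames(m) <- names(index)
  rownames(m) <- NULL
  m
}

#' Feature terms of a record as a token sequence
#'
#' The disease classifier consumes the extracted entities and their
#' relationships as a token sequence: every canonical entity term in record
#' order, with a dated symptom's compound `symptom#duration` token following
#' its bare term.
#'
#' @param record a `tcmRecord`.
#' @return character vector of tokens.
#' @export
entityTokens <- function(record) {
  if (nrow(record) == 0L) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(record))) {
    out <- c(out, record$canonical[i])
    if (record$type[i] == "symptom" && !is.na(record$duration[i])) {
      out <- c(out, paste0(record$canonical[i], "#", record$duration[i]))
    }
  }
  out
}
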