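#' Normalize full-width characters to half-width
#'
#' Clinical text mixes full-width and half-width encodings of the same
#' characters; downstream matching requires a single convention. Maps the
#' full-width forms U+FF01..U+FF5E to their ASCII equivalents and the
#' ideographic space U+3000 to a plain space. Idempotent and
#' length-preserving (each full-width character maps to exactly one
#' half-width character, so entity span offsets survive normalization).
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalizeWidth("ａｂｃ") # "abc"
normalizeWidth <- function(text) {
  vapply(text, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    cp <- utf8ToInt(s)
    fw <- cp >= 0xFF01L & cp <= 0xFF5EL
    cp[fw] <- cp[fw] - 0xFEE0L
    cp[cp == 0x3000L] <- 0x20L
    intToUtf8(cp)
  }, "", USE.NAMES = FALSE)
}

# does the string still contain configured full-width code points?
hasFullWidth <- function(text) {
  vapply(text, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    cp <- utf8ToInt(s)
    any((cp >= 0xFF01L & cp <= 0xFF5EL) | cp == 0x3000L)
  }, NA, USE.NAMES = FALSE)
}

#' Remove non-text placeholders from a note
#'
#' EHR exports embed non-text components (pictures, tables) that carry no
#' linguistic content; they appear here as placeholder tokens such as
#' `<img>`. Placeholder tokens are removed from every section, the remaining
#' text is re-joined in order, and the note's entity spans are shifted to
#' stay aligned with the edited text.
#'
#' @param note a `tcmNote`.
#' @param pattern regex a whole token must match to be considered non-text.
#' @return the cleaned `tcmNote`.
#' @export
stripNontext <- function(note, pattern = "^<[a-z]+>$") {
  for (nm in names(note$sections)) {
    tok <- tokenizeWithOffsets(note$sections[[nm]])
    if (nrow(tok) == 0L) next
    drop <- grepl(pattern, tok$token)
    if (!any(drop)) next
    keep <- tok[!drop, , drop = FALSE]
    newText <- paste(keep$token, collapse = " ")
    # old offset -> new offset for surviving tokens
    if (nrow(keep)) {
      lens <- nchar(keep$token)
      newStart <- c(0L, cumsum(lens + 1L)[-length(lens)])
      idx <- which(note$spans$section == nm)
      if (length(idx)) {
        j <- match(note$spans$start[idx], keep$start)
        w <- note$spans$end[idx] - note$spans$start[idx]
        ok <- !is.na(j)
        note$spans$start[idx[ok]] <- newStart[j[ok]]
        note$spans$end[idx[ok]] <- newStart[j[ok]] + w[ok]
        if (any(!ok)) {
          # spans that covered a removed placeholder are dropped
          note$spans <- note$spans[-idx[!ok], , drop = FALSE]
        }
      }
    } else {
      note$spans <- note$spans[note$spans$section != nm, , drop = FALSE]
    }
    note$sections[[nm]] <- newText
    rownames(note$spans) <- NULL
  }
  note
}

#' Split raw freestyle text into predefined sections
#'
#' Scans for `[section_name]` marker lines from `headerSpec` and assigns every
#' character of the input to exactly one section; text before the first marker
#' goes to a `preamble` section. A duplicated marker concatenates its contents
#' under the one section name (with a logged warning); sections absent from
#' the text are simply absent from the result.
#'
#' @param rawText a single string.
#' @param headerSpec ordered character vector of recognized section names.
#' @return a named list of section texts (a sectioned note).
#' @export
splitSections <- function(rawText, headerSpec = tcmSections()) {
  stopifnot(is.character(rawText), length(rawText) == 1L)
  lines <- strsplit(rawText, "\n", fixed = TRUE)[[1]]
  sections <- list()
  cur <- "preamble"
  buf <- character(0)
  commit <- function(sections, cur, buf) {
    if (!length(buf)) return(sections)
    txt <- paste(buf, collapse = "\n")
    if (!is.null(sections[[cur]])) {
      tcmLog("duplicated section marker '%s'; contents concatenated", cur)
      sections[[cur]] <- paste(sections[[cur]], txt, sep = "\n")
    } else {
      sections[[cur]] <- txt
    }
    sections
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\[([A-Za-z_]+)\\]\\s*$", ln))[[1]]
    if (length(m) == 2L && m[2] %in% headerSpec) {
      sections <- commit(sections, cur, buf)
      cur <- m[2]
      buf <- character(0)
      if (is.null(sections[[cur]])) sections[cur] <- list(NULL)
    } else {
      buf <- c(buf, ln)
    }
  }
  sections <- commit(sections, cur, buf)
  # markers followed by no text become empty sections
  sections <- lapply(sections, function(s) if (is.null(s)) "" else s)
  sections
}

# parse "key=value" fields from an admission/discharge page
parsePageFields <- function(text) {
  tok <- tokenizeWithOffsets(normalizeWidth(text))$token
  kv <- regmatches(tok, regexec("^([A-Za-z_]+)=(\\S+)$", tok))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}

# a standard chief complaint: at least one symptom-like token immediately
# followed by a duration token ("<n>-days|months|years")
durationPattern <- function() "^[0-9]+-(days|months|years)$"

isStandardComplaint <- function(text) {
  tok <- tokenizeWithOffsets(normalizeWidth(text))$token
  if (length(tok) < 2L) return(FALSE)
  isDur <- grepl(durationPattern(), tok)
  any(isDur[-1L] & !isDur[-length(isDur)])
}

#' Quality-control filter for a corpus
#'
#' Reproduces the exclusion rules applied to the hospital corpus: a note is
#' discarded iff it (a) lacks an admission or discharge page (`incomplete`),
#' (b) has one of the configured fields differing between the admission and
#' discharge pages (`inconsistent`), or (c) has no chief complaint matching
#' the standard symptom-plus-duration pattern (`nonstandard_complaint`).
#' The first matching rule, in that order, is recorded as the reason.
#'
#' @param notes list of `tcmNote`.
#' @param consistencyFields page fields compared between admission and
#'   discharge.
#' @return a `tcmQcReport`: list with `kept` (note ids) and `discarded`
#'   (data.frame `note_id`, `reason`). Together they partition the input ids.
#' @export
qcFilter <- function(notes, consistencyFields = c("disease", "sex", "age")) {
  ids <- vapply(notes, `[[`, "", "note_id")
  reasons <- character(0); bad <- character(0)
  for (note in notes) {
    reason <- NA_character_
    if (is.null(note$sections$admission) || is.null(note$sections$discharge)) {
      reason <- "incomplete"
    } else {
      a <- parsePageFields(note$sections$admission)
      d <- parsePageFields(note$sections$discharge)
      for (f in consistencyFields) {
        if (!identical(unname(a[f]), unname(d[f]))) { reason <- "inconsistent"; break }
      }
      if (is.na(reason) &&
          (is.null(note$sections$chief_complaint) ||
           !isStandardComplaint(note$sections$chief_complaint))) {
        reason <- "nonstandard_complaint"
      }
    }
    if (!is.na(reason)) { bad <- c(bad, note$note_id); reasons <- c(reasons, reason) }
  }
  structure(
    list(kept = setdiff(ids, bad),
         discarded = data.frame(note_id = bad, reason = reasons,
                                stringsAsFactors = FALSE)),
    class = "tcmQcReport"
  )
}

#' @export
print.tcmQcReport <- function(x, ...) {
  cat(sprintf("tcmQcReport: %d kept, %d discarded\n",
              length(x$kept), nrow(x$discarded)))
  if (nrow(x$discarded)) print(table(x$discarded$reason))
  invisible(x)
}

#' Balance class sizes by downsampling and synthetic minority oversampling
#'
#' Every class is brought to exactly `targetPerClass` rows: classes above the
#' target are reduced by uniform sampling without replacement; classes below
#' it are augmented with synthetic-minority-oversampling interpolants
#' `x + u * (neighbor - x)` with `u ~ Uniform(0,1)` and the neighbor drawn
#' from the `k` nearest same-class rows (Euclidean distance). Synthetic rows
#' therefore lie on segments between same-class points. Applied to numeric
#' training vectors only, never to raw text or held-out data.
#'
#' @param x numeric matrix (rows = records).
#' @param labels class label per row.
#' @param targetPerClass target rows per class (>= 1).
#' @param seed integer seed.
#' @param k neighbors considered for interpolation.
#' @return list with `x` (matrix) and `labels`, each class at the target size.
#' @export
balanceClasses <- function(x, labels, targetPerClass, seed = 1L, k = 5L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), targetPerClass >= 1)
  withSeed(seed, {
    parts <- split(seq_len(nrow(x)), labels)
    outX <- list(); outY <- list()
    for (cl in names(parts)) {
      idx <- parts[[cl]]
      n <- length(idx)
      if (n > targetPerClass) {
        pick <- sort(sample(idx, targetPerClass))
        outX[[cl]] <- x[pick, , drop = FALSE]
      } else if (n == targetPerClass) {
        outX[[cl]] <- x[idx, , drop = FALSE]
      } else {
        if (n < 2L) {
          stop(sprintf("class '%s' has %d record(s); interpolation needs >= 2", cl, n),
               call. = FALSE)
        }
        xc <- x[idx, , drop = FALSE]
        need <- targetPerClass - n
        d <- as.matrix(stats::dist(xc))
        diag(d) <- Inf
        kk <- min(k, n - 1L)
        base <- sample.int(n, need, replace = TRUE)
        synth <- matrix(0, need, ncol(x))
        for (j in seq_len(need)) {
          b <- base[j]
          nb <- order(d[b, ])[seq_len(kk)]
          nb <- nb[sample.int(kk, 1L)]
          u <- stats::runif(1)
          synth[j, ] <- xc[b, ] + u * (xc[nb, ] - xc[b, ])
        }
        outX[[cl]] <- rbind(xc, synth)
      }
      outY[[cl]] <- rep(cl, targetPerClass)
    }
    list(x = do.call(rbind, unname(outX)), labels = unlist(outY, use.names = FALSE))
  })
}

#' Stratified 8:1:1 partition of note ids
#'
#' The validation and test sets each receive `floor(N * r / sum(ratios))` ids
#' (2298 of 22,984 at the default 8:1:1); the training set takes the
#' remainder. Within that constraint the split is stratified over `strata`
#' (the disease label) as evenly as integer rounding allows, allocating
#' leftover slots to the strata with the largest fractional quotas. The three
#' sets are disjoint and exhaust the input.
#'
#' @param ids unique identifiers.
#' @param strata stratification label per id (defaults to a single stratum).
#' @param ratios length-3 integer ratios (train, validation, test).
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` character vectors.
#' @export
partitionCorpus <- function(ids, strata = rep("all", length(ids)),
                            ratios = c(8, 1, 1), seed = 1L) {
  if (length(ids) == 0L) stop("cannot partition an empty id set", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  stopifnot(length(strata) == length(ids), length(ratios) == 3L)
  N <- length(ids)
  tot <- sum(ratios)
  nVal <- floor(N * ratios[2] / tot)
  nTest <- floor(N * ratios[3] / tot)
  withSeed(seed, {
    byStr <- split(seq_len(N), strata)
    byStr <- lapply(byStr, function(ix) ix[sample.int(length(ix))])
    takeStratified <- function(byStr, nTake) {
      avail <- lengths(byStr)
      quota <- nTake * avail / sum(avail)
      base <- pmin(floor(quota), avail)
      left <- nTake - sum(base)
      if (left > 0) {
        frac <- quota - floor(quota)
        room <- avail - base
        ord <- order(-frac, seq_along(byStr))
        for (s in ord) {
          if (left == 0) break
          add <- min(room[s], 1L)
          base[s] <- base[s] + add
          left <- left - add
        }
        # degenerate strata exhausted: spill anywhere with room
        while (left > 0) {
          s <- which(avail - base > 0)[1L]
          base[s] <- base[s] + 1L
          left <- left - 1L
        }
      }
      taken <- integer(0)
      for (s in seq_along(byStr)) {
        if (base[s] > 0) {
          taken <- c(taken, byStr[[s]][seq_len(base[s])])
          byStr[[s]] <- byStr[[s]][-seq_len(base[s])]
        }
      }
      list(taken = taken, rest = byStr)
    }
    v <- takeStratified(byStr, nVal)
    t <- takeStratified(v$rest, nTest)
    trainIdx <- sort(unlist(t$rest, use.names = FALSE))
    list(train = ids[trainIdx], val = ids[sort(v$taken)], test = ids[sort(t$taken)])
  })
}
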