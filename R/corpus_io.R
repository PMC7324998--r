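#' Write / read an annotated corpus as JSONL
#'
#' One JSON object per line with fields `id`, `sections`, `spans`, `disease`,
#' `syndrome`, `qc_flags`. `readCorpus(writeCorpus(x))` is the identity.
#'
#' @param notes list of `tcmNote`.
#' @param path file path.
#' @return `writeCorpus` returns the path invisibly; `readCorpus` a list of
#'   `tcmNote`.
#' @export
writeCorpus <- function(notes, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (note in notes) {
    obj <- list(
      id = jsonlite::unbox(note$note_id),
      sections = lapply(note$sections, jsonlite::unbox),
      spans = if (nrow(note$spans)) note$spans else list(),
      disease = jsonlite::unbox(note$disease),
      syndrome = jsonlite::unbox(note$syndrome),
      qc_flags = note$qc_flags
    )
    writeLines(as.character(jsonlite::toJSON(obj, dataframe = "rows", null = "null")),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("parse error at line %d of %s: %s",
                                 i, path, conditionMessage(e)), call. = FALSE)
                  })
    spans <- if (length(x$spans)) {
      data.frame(
        section = vapply(x$spans, function(s) as.character(s$section), ""),
        start = vapply(x$spans, function(s) as.integer(s$start), 0L),
        end = vapply(x$spans, function(s) as.integer(s$end), 0L),
        type = vapply(x$spans, function(s) as.character(s$type), ""),
        canonical = vapply(x$spans, function(s) as.character(s$canonical), ""),
        stringsAsFactors = FALSE
      )
    } else emptySpans()
    out[[i]] <- structure(
      list(note_id = as.character(x$id),
           sections = lapply(x$sections, as.character),
           spans = spans,
           disease = as.character(x$disease),
           syndrome = as.character(x$syndrome),
           qc_flags = as.character(unlist(x$qc_flags))),
      class = "tcmNote"
    )
  }
  out
}

# BIO tags for one tokenized section given its character spans
bioTags <- function(tok, spans) {
  tags <- rep("O", nrow(tok))
  if (nrow(spans) == 0L) return(tags)
  for (i in seq_len(nrow(spans))) {
    inside <- tok$start >= spans$start[i] & tok$end <= spans$end[i]
    idx <- which(inside)
    if (length(idx)) {
      tags[idx] <- paste0("I-", spans$type[i])
      tags[idx[1L]] <- paste0("B-", spans$type[i])
    }
  }
  tags
}

#' Write / read CoNLL-style BIO annotations
#'
#' Two tab-separated columns (token, BIO tag), one blank-line-separated block
#' per section, each block preceded by a `# note=<id> section=<name>` comment.
#'
#' @param notes list of `tcmNote`.
#' @param path file path.
#' @return `writeConll` returns the path invisibly; `readConll` a list of
#'   blocks, each a list with `note_id`, `section`, `tokens`, `tags`.
#' @export
writeConll <- function(notes, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (note in notes) {
    for (nm in names(note$sections)) {
      tok <- tokenizeWithOffsets(note$sections[[nm]])
      sp <- note$spans[note$spans$section == nm, , drop = FALSE]
      tags <- bioTags(tok, sp)
      writeLines(c(sprintf("# note=%s section=%s", note$note_id, nm),
                   paste(tok$token, tags, sep = "\t"), ""),
                 con, useBytes = TRUE)
    }
  }
  invisible(path)
}

#' @rdname writeConll
#' @export
readConll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur$tokens)) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) {
      blocks <- flush(cur, blocks); cur <- NULL
    } else if (startsWith(ln, "#")) {
      blocks <- flush(cur, blocks)
      m <- regmatches(ln, regexec("^# note=(\\S+) section=(\\S+)$", ln))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("parse error at line %d of %s: malformed comment", i, path),
             call. = FALSE)
      }
      cur <- list(note_id = m[2], section = m[3],
                  tokens = character(0), tags = character(0))
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop(sprintf("parse error at line %d of %s: expected 2 tab-separated fields",
                     i, path), call. = FALSE)
      }
      if (is.null(cur)) cur <- list(note_id = NA_character_, section = NA_character_,
                                    tokens = character(0), tags = character(0))
      cur$tokens <- c(cur$tokens, parts[1])
      cur$tags <- c(cur$tags, parts[2])
    }
  }
  flush(cur, blocks)
}
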