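#' @keywords internal
"_PACKAGE"

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package funnel through this helper so that
#' a function called with the same seed is bit-reproducible and never perturbs
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# numerically stable log(sum(exp(x))); -Inf-safe
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Package log messages
#'
#' Emits a classed condition (`tcmdx_log`) via `message()`; callers and tests
#' can suppress or capture them.
#' @noRd
tcmLog <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(structure(
    class = c("tcmdx_log", "message", "condition"),
    list(message = paste0("[tcmdx] ", msg, "\n"), call = NULL)
  ))
  invisible(msg)
}

#' Tokenize text on whitespace, tracking character offsets
#'
#' The default tokenizer used throughout: splits on runs of whitespace and
#' returns 0-based, half-open character offsets into the original string, so
#' token-level tags can be mapped back to character spans losslessly.
#'
#' @param text a single string.
#' @return a data.frame with columns `token`, `start`, `end` (0-based,
#'   half-open).
#' @export
#' @examples
#' tokenizeWithOffsets("cough 3-days")
tokenizeWithOffsets <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(
    token = substring(text, m, m + lens - 1L),
    start = starts,
    end = starts + lens,
    stringsAsFactors = FALSE
  )
}

# stable ranked order: by score descending, then by index ascending
orderDesc <- function(score) order(-score, seq_along(score))
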