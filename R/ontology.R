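#' Build a random many-to-many disease/syndrome ontology
#'
#' In traditional Chinese medicine one disease presents as several syndromes
#' and one syndrome can occur under several diseases. This constructs a random
#' ontology with that many-to-many structure: each disease is assigned a
#' non-empty set of syndromes, every syndrome is used by at least one disease
#' (when the counts allow), and whenever the requested per-disease set sizes
#' exceed the syndrome inventory at least one syndrome is shared between
#' diseases.
#'
#' @param nDiseases number of diseases (>= 1).
#' @param nSyndromes number of syndromes (>= 1).
#' @param meanSyndromesPerDisease target mean size of a disease's syndrome set
#'   (>= 1).
#' @param seed integer seed; the ontology is deterministic given the arguments.
#' @return an object of class `tcmOntology`: a list with `diseases`,
#'   `syndromes` (character vectors of opaque labels) and `map` (named list,
#'   disease -> character vector of syndromes).
#' @export
#' @examples
#' ont <- buildOntology(4, 6, 2, seed = 1)
#' ont$map
buildOntology <- function(nDiseases, nSyndromes, meanSyndromesPerDisease, seed = 1L) {
  if (!is.numeric(nDiseases) || nDiseases < 1 ||
      !is.numeric(nSyndromes) || nSyndromes < 1 ||
      !is.numeric(meanSyndromesPerDisease) || meanSyndromesPerDisease < 1) {
    stop("nDiseases, nSyndromes and meanSyndromesPerDisease must all be >= 1",
         call. = FALSE)
  }
  nDiseases <- as.integer(nDiseases)
  nSyndromes <- as.integer(nSyndromes)
  diseases <- sprintf("D%02d", seq_len(nDiseases))
  syndromes <- sprintf("S%02d", seq_len(nSyndromes))
  withSeed(seed, {
    # per-disease set sizes around the mean, each at least 1
    sizes <- pmax(1L, pmin(nSyndromes, stats::rpois(nDiseases, meanSyndromesPerDisease)))
    map <- vector("list", nDiseases)
    names(map) <- diseases
    # first pass: deal every syndrome out so each is used at least once
    owner <- rep(seq_len(nDiseases), length.out = nSyndromes)
    for (i in seq_len(nDiseases)) map[[i]] <- syndromes[owner == i]
    # second pass: top up to the drawn sizes by sampling the full inventory
    for (i in seq_len(nDiseases)) {
      need <- sizes[i] - length(map[[i]])
      if (need > 0) {
        pool <- setdiff(syndromes, map[[i]])
        map[[i]] <- sort(c(map[[i]], sample(pool, min(need, length(pool)))))
      } else {
        map[[i]] <- sort(map[[i]])
      }
      if (length(map[[i]]) == 0L) map[[i]] <- sample(syndromes, 1L)
    }
    # enforce sharing when it must exist: with >= 2 diseases and fewer
    # syndromes than total slots, at least one syndrome serves two diseases
    if (nDiseases >= 2L && !anyShared(map)) {
      s <- map[[1L]][1L]
      map[[2L]] <- sort(unique(c(map[[2L]], s)))
    }
    ont <- structure(
      list(diseases = diseases, syndromes = syndromes, map = map),
      class = "tcmOntology"
    )
    validateOntology(ont)
    ont
  })
}

anyShared <- function(map) {
  all_s <- unlist(map, use.names = FALSE)
  any(duplicated(all_s))
}

validateOntology <- function(ont) {
  stopifnot(inherits(ont, "tcmOntology"))
  if (!all(lengths(ont$map) >= 1L)) stop("every disease must map to >= 1 syndrome")
  if (!setequal(names(ont$map), ont$diseases)) stop("map keys must equal diseases")
  if (!all(unlist(ont$map) %in% ont$syndromes)) stop("map values must be known syndromes")
  invisible(ont)
}

#' @export
print.tcmOntology <- function(x, ...) {
  cat(sprintf("tcmOntology: %d diseases, %d syndromes, %d disease-syndrome links\n",
              length(x$diseases), length(x$syndromes), sum(lengths(x$map))))
  shared <- sum(table(unlist(x$map)) >= 2L)
  cat(sprintf("  syndromes shared by >=2 diseases: %d\n", shared))
  invisible(x)
}

#' Write / read an ontology as JSON
#' @param ont a `tcmOntology`.
#' @param path file path.
#' @return `readOntology` returns a `tcmOntology`; `writeOntology` returns the
#'   path invisibly.
#' @export
writeOntology <- function(ont, path) {
  validateOntology(ont)
  jsonlite::write_json(
    list(diseases = ont$diseases, syndromes = ont$syndromes, map = ont$map),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname writeOntology
#' @export
readOntology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ont <- structure(
    list(diseases = as.character(x$diseases),
         syndromes = as.character(x$syndromes),
         map = lapply(x$map, as.character)),
    class = "tcmOntology"
  )
  validateOntology(ont)
  ont
}
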