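# shared helpers: sentence segmentation, stopwords, token-set Jaccard

# abbreviations that must not terminate a sentence
.abbrev_guard <- c("e.g.", "i.e.", "et al.", "vs.", "cf.", "Fig.", "Figs.",
                   "Dr.", "No.", "approx.", "ca.", "sp.", "spp.", "St.")

#' Split text into sentences
#'
#' Splits at sentence-final punctuation (`.`, `!`, `?`) followed by whitespace
#' and an uppercase letter or digit, guarding a small list of common
#' abbreviations ("e.g.", "et al.", ...).
#'
#' @param text a single character string.
#' @return character vector of sentences (empty for blank input).
#' @export
split_sentences <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  protected <- text
  for (i in seq_along(.abbrev_guard)) {
    protected <- gsub(.abbrev_guard[i],
                      gsub(".", "\x01", .abbrev_guard[i], fixed = TRUE),
                      protected, fixed = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  trimws(parts[nzchar(trimws(parts))])
}

#' Default stopword list
#'
#' Returns the stopword list shipped with the package (one term per line,
#' lowercase). Pass `path` to load a user-supplied list instead.
#'
#' @param path optional path to a stopword file.
#' @return character vector of stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords.txt", package = "storyline")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("stopword file not found: ", path)
  }
  out <- readLines(path, warn = FALSE)
  out <- trimws(out)
  out[nzchar(out)]
}

#' Default indicator-phrase lexicon
#'
#' Phrases whose presence in an abstract sentence hints at its rhetorical role
#' (background/context vs. findings/results). The lexicon is configuration:
#' replace it with any phrase list relevant to your corpus.
#'
#' @param path optional path to a phrase file (one phrase per line).
#' @return character vector of lowercase phrases.
#' @export
default_phrase_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indicator_phrases.txt", package = "storyline")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("phrase lexicon file not found: ", path)
  }
  out <- tolower(trimws(readLines(path, warn = FALSE)))
  out[nzchar(out)]
}

# Jaccard coefficient of two sets (character vectors); 0 when both empty
.jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# full text of a document (title + abstract sentences)
.doc_text <- function(doc) paste(c(doc$title, doc$sentences), collapse = " ")

# abstract text only
.abstract_text <- function(doc) paste(doc$sentences, collapse = " ")
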