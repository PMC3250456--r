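#' Tokenize and stem text
#'
#' Lowercases, splits on non-alphanumeric characters, removes stopwords,
#' pure-numeral tokens (measurements) and DNA-like tokens (six or more
#' characters drawn solely from A/C/G/T), then Porter-stems what remains.
#' Alphanumeric gene-style tokens such as "p53" are kept.
#'
#' @param text character string (may be empty).
#' @param stopwords character vector of stopwords (matched pre-stemming).
#' @return character vector of stemmed terms (possibly with duplicates).
#' @export
tokenize_and_stem <- function(text, stopwords = default_stopwords()) {
  if (is.null(text) || length(text) == 0L) return(character(0))
  text <- tolower(paste(text, collapse = " "))
  toks <- strsplit(text, "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% stopwords]
  toks <- toks[!grepl("^[0-9]+$", toks)]
  toks <- toks[!grepl("^[acgt]{6,}$", toks)]
  porter_stem(toks)
}

#' Build tf-idf term vectors for a corpus
#'
#' Models each document (title plus abstract) as a sparse vector of
#' nonnegative term weights: the raw weight of term t in document d is
#' `f_td * ln(N / n_t)` (term frequency times inverse document frequency,
#' natural log), and vectors are cosine (L2) normalized so that longer
#' abstracts do not dominate. Terms present in every document receive zero
#' weight and drop out of the vectors.
#'
#' @param corpus a `story_corpus`.
#' @param stopwords stopword list used by the tokenizer.
#' @return a `story_vectors` object: `$vectors` is a named list (doc_id ->
#'   named numeric vector of positive weights, unit Euclidean norm unless
#'   empty); `$vocabulary` holds the per-term document frequencies `n_t` and
#'   corpus size `N`.
#' @export
build_vectors <- function(corpus, stopwords = default_stopwords()) {
  stopifnot(inherits(corpus, "story_corpus"))
  docs <- corpus$documents
  if (length(docs) == 0L) stop("corpus is empty")
  counts <- lapply(docs, function(d) {
    toks <- tokenize_and_stem(.doc_text(d), stopwords)
    if (length(toks) == 0L) return(integer(0))
    tab <- table(toks)
    stats::setNames(as.integer(tab), names(tab))
  })
  N <- length(docs)
  df <- table(unlist(lapply(counts, names), use.names = FALSE))
  doc_frequency <- stats::setNames(as.integer(df), names(df))
  idf <- log(N / doc_frequency)
  vectors <- lapply(counts, function(ct) {
    if (length(ct) == 0L) return(stats::setNames(numeric(0), character(0)))
    w <- ct * idf[names(ct)]
    w <- w[w > 0]
    if (length(w) == 0L) return(stats::setNames(numeric(0), character(0)))
    w / sqrt(sum(w^2))
  })
  structure(list(
    vectors = vectors,
    vocabulary = list(doc_frequency = doc_frequency, n_docs = N)
  ), class = "story_vectors")
}

#' @export
print.story_vectors <- function(x, ...) {
  cat("<story_vectors> ", length(x$vectors), " documents, ",
      length(x$vocabulary$doc_frequency), " terms\n", sep = "")
  invisible(x)
}

#' Soergel distance between two sparse term vectors
#'
#' `D(u, v) = sum_t |u_t - v_t| / sum_t max(u_t, v_t)` over the union of
#' stored terms. A true metric on nonnegative vectors: 0 exactly when the
#' vectors are identical, 1 exactly when their term sets are disjoint,
#' symmetric, and obeying the triangle inequality (which is what makes the
#' straight-line heuristic of [astar_story()] admissible).
#'
#' @param u,v named numeric vectors of nonnegative term weights.
#' @return distance in `[0, 1]`.
#' @export
soergel_distance <- function(u, v) {
  if (length(u) == 0L && length(v) == 0L) {
    stop("Soergel distance is undefined for two empty vectors")
  }
  terms <- union(names(u), names(v))
  uu <- vv <- numeric(length(terms))
  uu[match(names(u), terms)] <- u
  vv[match(names(v), terms)] <- v
  sum(abs(uu - vv)) / sum(pmax(uu, vv))
}

# memoized pairwise Soergel lookup over a story_vectors object
.soergel_cache <- function(vectors) {
  memo <- new.env(parent = emptyenv())
  function(a, b) {
    if (a == b) return(0)
    key <- if (a < b) paste0(a, "\x1f", b) else paste0(b, "\x1f", a)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    d <- soergel_distance(vectors$vectors[[a]], vectors$vectors[[b]])
    memo[[key]] <- d
    d
  }
}

#' Write vectors to plain-text files
#'
#' Persists the sparse term-weight matrix in a MatrixMarket-style coordinate
#' triplet file plus TSV indices for terms and documents.
#'
#' @param vectors a `story_vectors` object.
#' @param prefix output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.terms.tsv` and `<prefix>.docs.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_vectors <- function(vectors, prefix) {
  stopifnot(inherits(vectors, "story_vectors"))
  terms <- sort(names(vectors$vocabulary$doc_frequency))
  docs <- names(vectors$vectors)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_along(docs)) {
    v <- vectors$vectors[[i]]
    if (length(v) == 0L) next
    rows <- c(rows, rep(i, length(v)))
    cols <- c(cols, match(names(v), terms))
    vals <- c(vals, unname(v))
  }
  con <- file(paste0(prefix, ".mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               paste(length(docs), length(terms), length(vals))), con)
  writeLines(sprintf("%d %d %.10g", rows, cols, vals), con)
  close(con)
  writeLines(paste(seq_along(terms), terms, sep = "\t"),
             paste0(prefix, ".terms.tsv"))
  writeLines(paste(seq_along(docs), docs, sep = "\t"),
             paste0(prefix, ".docs.tsv"))
  invisible(prefix)
}
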