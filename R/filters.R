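# post-search story filters: context overlap and entity-level sentence
# cohesion

#' Context overlap filter
#'
#' A coherent story should keep a consistent experimental context from one
#' document to the next. For every consecutive pair of story documents this
#' computes the Jaccard coefficient between the stemmed, stopword-free token
#' sets of their concatenated context sentences (as labeled by the sentence
#' classifier); the story passes only if every link reaches `j_min`. A
#' document with no context sentences scores 0 on its links.
#'
#' @param chain a `clique_chain` (or character vector of junction doc_ids).
#' @param corpus the `story_corpus` holding the documents.
#' @param model a trained `sentence_nb` classifier.
#' @param j_min minimum per-link Jaccard coefficient (default 0.05).
#' @param stopwords stopword list for tokenization.
#' @return list with `pass` (logical), `link_scores` (numeric, one per
#'   consecutive pair) and `labels` (per-document sentence labels).
#' @export
context_overlap_filter <- function(chain, corpus, model, j_min = 0.05,
                                   stopwords = default_stopwords()) {
  junctions <- if (inherits(chain, "clique_chain")) chain$junctions else chain
  docs <- corpus$documents[junctions]
  if (any(vapply(docs, is.null, logical(1)))) {
    stop("chain documents missing from corpus")
  }
  labels <- lapply(docs, function(d) {
    tab <- .sentence_table(list(d))
    classify_sentences(model, tab)
  })
  token_sets <- lapply(seq_along(docs), function(i) {
    ctx <- docs[[i]]$sentences[labels[[i]] == "context"]
    if (length(ctx) == 0L) return(character(0))
    unique(tokenize_and_stem(paste(ctx, collapse = " "), stopwords))
  })
  n <- length(docs)
  scores <- vapply(seq_len(n - 1L), function(i) {
    a <- token_sets[[i]]; b <- token_sets[[i + 1L]]
    if (length(a) == 0L || length(b) == 0L) return(0)
    .jaccard(a, b)
  }, numeric(1))
  list(pass = all(scores >= j_min), link_scores = scores,
       labels = stats::setNames(labels, junctions))
}

#' Annotate sentences with named entities
#'
#' Default recognizer: case-insensitive longest-match dictionary lookup
#' against a gazetteer, on word boundaries; when candidate matches overlap
#' ("pyruvate kinase" vs "kinase") only the longest is kept. Any external
#' recognizer can be substituted by supplying its output in the same shape.
#'
#' @param docs list of `story_document`s (or a `story_corpus`).
#' @param gazetteer character vector of entity names.
#' @return an `entity_annotation`: named list doc_id -> list of per-sentence
#'   entity character vectors (index 1 is the title).
#' @export
annotate_entities <- function(docs, gazetteer) {
  if (inherits(docs, "story_corpus")) docs <- docs$documents
  if (length(gazetteer) == 0L) {
    stop("gazetteer is required for the default entity recognizer")
  }
  gaz <- gazetteer[order(-nchar(gazetteer), gazetteer)]
  ann <- lapply(docs, function(d) {
    sents <- c(d$title, d$sentences)
    lapply(sents, .match_entities, gaz = gaz)
  })
  names(ann) <- vapply(docs, `[[`, character(1), "doc_id")
  structure(ann, class = "entity_annotation")
}

# longest-match gazetteer lookup in one sentence; gaz sorted by nchar desc
.match_entities <- function(sentence, gaz) {
  low <- tolower(sentence)
  found <- character(0)
  for (g in gaz) {
    pat <- paste0("(?<![a-z0-9])", .regex_escape(tolower(g)), "(?![a-z0-9])")
    m <- gregexpr(pat, low, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    found <- c(found, g)
    # blank out matched spans so shorter overlapping entities cannot match
    for (i in seq_along(m)) {
      s <- m[i]; e <- s + attr(m, "match.length")[i] - 1L
      substr(low, s, e) <- paste(rep(" ", e - s + 1L), collapse = "")
    }
  }
  sort(unique(found))
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Sentence cohesion filter
#'
#' Builds a layered graph whose layer i holds the sentences of the i-th
#' story document, with an edge between sentences of consecutive layers
#' whenever their named-entity sets intersect. The story passes if a
#' start-to-end path exists (breadth-first reachability); on a pass the
#' filter also returns the path maximizing the summed per-edge entity
#' Jaccard coefficients, breaking ties toward the earliest sentence
#' positions. Stories with no such entity-linked sentence path are
#' eliminated.
#'
#' @param chain a `clique_chain` (or character vector of junction doc_ids).
#' @param annotations an `entity_annotation` covering all story documents.
#' @return list with `pass` (logical), `path` (data.frame doc_id/position/
#'   entities for the best sentence path, NULL on fail) and `score` (summed
#'   edge Jaccard, NA on fail). Positions are 0-based abstract sentence
#'   indices; the title is excluded from the path layers.
#' @export
cohesion_filter <- function(chain, annotations) {
  junctions <- if (inherits(chain, "clique_chain")) chain$junctions else chain
  if (!all(junctions %in% names(annotations))) {
    stop("annotations do not cover all story documents")
  }
  # layer i: entity sets of the abstract sentences of junction i
  layers <- lapply(junctions, function(id) annotations[[id]][-1L])
  n <- length(layers)
  if (n < 2L) stop("a story needs at least two documents")

  # forward DP: best (score, path) per sentence of the current layer;
  # ties resolved toward lexicographically earliest position sequences
  best_score <- rep(0, length(layers[[1L]]))
  best_path <- lapply(seq_along(layers[[1L]]), function(s) s)
  reachable <- rep(TRUE, length(layers[[1L]]))
  for (i in seq_len(n - 1L)) {
    nxt <- layers[[i + 1L]]
    ns <- length(nxt)
    new_score <- rep(-Inf, ns)
    new_path <- vector("list", ns)
    for (t in seq_len(ns)) {
      if (length(nxt[[t]]) == 0L) next
      for (s in seq_along(layers[[i]])) {
        if (!reachable[s]) next
        j <- .jaccard(layers[[i]][[s]], nxt[[t]])
        if (j <= 0) next
        sc <- best_score[s] + j
        cand <- c(best_path[[s]], t)
        if (sc > new_score[t] + 1e-12 ||
            (abs(sc - new_score[t]) <= 1e-12 &&
             .path_earlier(cand, new_path[[t]]))) {
          new_score[t] <- sc
          new_path[[t]] <- cand
        }
      }
    }
    best_score <- new_score
    best_path <- new_path
    reachable <- is.finite(new_score)
    if (!any(reachable)) {
      return(list(pass = FALSE, path = NULL, score = NA_real_))
    }
  }
  win <- NA_integer_
  for (t in which(reachable)) {
    if (is.na(win) || best_score[t] > best_score[win] + 1e-12 ||
        (abs(best_score[t] - best_score[win]) <= 1e-12 &&
         .path_earlier(best_path[[t]], best_path[[win]]))) {
      win <- t
    }
  }
  idx <- best_path[[win]]
  path <- data.frame(doc_id = junctions, position = idx - 1L,
                     stringsAsFactors = FALSE)
  path$entities <- lapply(seq_len(n), function(i) layers[[i]][[idx[i]]])
  list(pass = TRUE, path = path, score = best_score[win])
}

# TRUE if integer path a orders before b (b may be NULL)
.path_earlier <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}
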