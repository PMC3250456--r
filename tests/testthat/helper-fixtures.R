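# fixtures and independent oracles used across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a named list of named numeric vectors as a story_vectors object
as_vectors <- function(vecs) {
  terms <- unique(unlist(lapply(vecs, names)))
  df <- table(unlist(lapply(vecs, names)))
  structure(list(
    vectors = vecs,
    vocabulary = list(doc_frequency = stats::setNames(as.integer(df),
                                                      names(df)),
                      n_docs = length(vecs))
  ), class = "story_vectors")
}

# random sparse nonnegative vectors over a shared term pool
random_sparse_vectors <- function(n, n_terms = 30L, min_k = 3L, max_k = 8L) {
  pool <- sprintf("t%02d", seq_len(n_terms))
  vecs <- lapply(seq_len(n), function(i) {
    k <- sample(min_k:max_k, 1L)
    stats::setNames(stats::runif(k, 0.05, 1), sample(pool, k))
  })
  names(vecs) <- sprintf("d%03d", seq_len(n))
  as_vectors(vecs)
}

# direct-summation Soergel oracle (independent of the package formulation)
soergel_oracle <- function(u, v) {
  terms <- union(names(u), names(v))
  s_abs <- 0; s_max <- 0
  for (t in terms) {
    a <- if (t %in% names(u)) u[[t]] else 0
    b <- if (t %in% names(v)) v[[t]] else 0
    s_abs <- s_abs + abs(a - b)
    s_max <- s_max + max(a, b)
  }
  s_abs / s_max
}

# brute-force closed-itemset enumeration over a small binary matrix:
# every nonempty term subset that equals its own closure and meets support
brute_closed_sets <- function(mat, min_support) {
  terms <- colnames(mat)
  docs <- rownames(mat)
  n <- nrow(mat)
  out <- list()
  for (mask in seq_len(2^length(terms) - 1L)) {
    sel <- terms[bitwAnd(mask, 2^(seq_along(terms) - 1L)) > 0L]
    supp <- docs[apply(mat[, sel, drop = FALSE] > 0, 1L, all)]
    if (length(supp) < min_support * n - 1e-9) next
    closure <- terms[apply(mat[supp, , drop = FALSE] > 0, 2L, all)]
    if (setequal(closure, sel)) {
      out[[length(out) + 1L]] <- list(docs = sort(supp), terms = sort(sel))
    }
  }
  out
}

# canonical string form of a concept set for comparison
concept_keys <- function(concepts) {
  sort(vapply(concepts, function(cc) {
    paste(paste(sort(cc$docs), collapse = ","),
          paste(sort(cc$terms), collapse = ","), sep = "|")
  }, character(1)))
}

# exhaustive branch-and-bound search over the same successor structure as
# the A* (independent of the best-first machinery): minimal cumulative
# Soergel cost over simple junction paths, Inf when no story exists
oracle_optimal_cost <- function(start, end, params, index, vectors) {
  dist <- function(a, b) soergel_distance(vectors$vectors[[a]],
                                          vectors$vectors[[b]])
  memo <- new.env(parent = emptyenv())
  get_succ <- function(doc) {
    hit <- memo[[doc]]
    if (!is.null(hit)) return(hit)
    cls <- generate_successors(doc, params, index, vectors)
    nxt <- unique(unlist(lapply(cls, function(cl) setdiff(cl$members, doc))))
    if (is.null(nxt)) nxt <- character(0)
    memo[[doc]] <- nxt
    nxt
  }
  best <- Inf
  rec <- function(doc, g, visited) {
    if (g >= best) return(invisible())
    if (doc == end) { best <<- g; return(invisible()) }
    for (nx in get_succ(doc)) {
      if (nx %in% visited) next
      rec(nx, g + dist(doc, nx), c(visited, nx))
    }
  }
  rec(start, 0, start)
  best
}

# tiny corpus builder from a named list of term character vectors; terms are
# stem-stable tokens, every doc gets one context and one result sentence
corpus_from_terms <- function(term_sets) {
  docs <- lapply(names(term_sets), function(id) {
    tm <- term_sets[[id]]
    story_document(id, title = paste("On", tm[1]),
                   sentences = c(paste0("In this work on ",
                                        paste(tm, collapse = " "), "."),
                                 "We observed it."),
                   mesh_terms = tm[1])
  })
  names(docs) <- names(term_sets)
  structure(list(documents = docs,
                 provenance = list(source = "in-memory")),
            class = "story_corpus")
}

# staggered five-document story used for dispersion examples: adjacent pairs
# overlap, non-adjacent pairs are disjoint except A-C which share a weak term
staggered_story_vectors <- function() {
  as_vectors(list(
    A = c(t1 = 1, q = 1),
    B = c(t1 = 1, t2 = 1),
    C = c(t2 = 1, t3 = 1, q = 1),
    D = c(t3 = 1, t4 = 1),
    E = c(t4 = 1, t5 = 1)
  ))
}

# write a small JSONL corpus file and return its path
write_jsonl_fixture <- function(records, path = tempfile(fileext = ".jsonl")) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  path
}

jsonl_record <- function(doc_id, title = "A title of things",
                         abstract = "First sentence here. Second one there.",
                         mesh_terms = c("Thing"),
                         publication_types = "Journal Article") {
  list(doc_id = doc_id, title = title, abstract = abstract,
       mesh_terms = mesh_terms, publication_types = publication_types)
}
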