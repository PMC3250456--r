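#' Mine closed itemsets (concepts) from a binary term-document matrix
#'
#' A concept is a maximal (document set, term set) pair: the documents are
#' exactly those containing all the terms, and the terms exactly those shared
#' by all the documents. The miner enumerates every closed term set with
#' relative support at least `min_support` via the intersection method (every
#' closed set is the intersection of the term sets of the documents that
#' contain it), which is output-equivalent to CHARM-style miners. The empty
#' term set is never reported.
#'
#' @param x either a logical/0-1 matrix (rows = documents, columns = terms,
#'   with dimnames) or a `story_vectors` object, which is binarized as
#'   "term present iff modeled weight > 0".
#' @param min_support minimum relative support in `(0, 1]`. The default
#'   targets an expected support count of about 2 documents.
#' @return a `concept_index`: `$concepts` is a list of
#'   `list(docs = <chr>, terms = <chr>)`; `$per_doc` maps each doc_id to the
#'   indices of its concepts ordered by decreasing term-set size (ties broken
#'   by lexicographically smallest term set).
#' @export
mine_concepts <- function(x, min_support = NULL) {
  sets <- .doc_term_sets(x)
  n_docs <- length(sets)
  if (n_docs == 0L) stop("matrix is empty")
  if (is.null(min_support)) min_support <- min(1, 2 / n_docs)
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }

  # integer-coded term universe for fast sorted-set intersections
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  isets <- lapply(sets, function(s) sort(match(s, universe)))

  # intersection method: every closed term set (with nonempty support) is an
  # intersection of some subset of document term sets
  closed <- new.env(parent = emptyenv())
  for (s in isets) {
    if (length(s) == 0L) next
    cand <- list(s)
    for (key in ls(closed)) {
      it <- .int_intersect(closed[[key]], s)
      if (length(it) > 0L) cand[[length(cand) + 1L]] <- it
    }
    for (cs in cand) {
      closed[[paste(cs, collapse = ",")]] <- cs
    }
  }

  keys <- ls(closed)
  concepts <- list()
  min_count <- min_support * n_docs - 1e-9
  for (key in keys) {
    ts <- closed[[key]]
    supp <- which(vapply(isets, function(s) all(ts %in% s), logical(1)))
    if (length(supp) >= min_count) {
      concepts[[length(concepts) + 1L]] <- list(
        docs = names(sets)[supp],
        terms = universe[ts]
      )
    }
  }
  if (length(concepts) == 0L) {
    warning("min_support too high: no concept survives")
  }

  # deterministic global order: |terms| desc, then lexicographic term key
  term_keys <- vapply(concepts, function(cc) paste(cc$terms, collapse = " "),
                      character(1))
  sizes <- vapply(concepts, function(cc) length(cc$terms), integer(1))
  ord <- order(-sizes, term_keys)
  concepts <- concepts[ord]

  per_doc <- stats::setNames(vector("list", n_docs), names(sets))
  for (ci in seq_along(concepts)) {
    for (d in concepts[[ci]]$docs) {
      per_doc[[d]] <- c(per_doc[[d]], ci)
    }
  }
  structure(list(concepts = concepts, per_doc = per_doc,
                 min_support = min_support, n_docs = n_docs),
            class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat("<concept_index> ", length(x$concepts), " concepts over ", x$n_docs,
      " documents (min_support = ", signif(x$min_support, 3), ")\n", sep = "")
  invisible(x)
}

# intersect two sorted integer vectors
.int_intersect <- function(a, b) a[a %in% b]

.doc_term_sets <- function(x) {
  if (inherits(x, "story_vectors")) {
    return(lapply(x$vectors, names))
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("binary matrix needs row (document) and column (term) names")
    }
    return(stats::setNames(
      lapply(seq_len(nrow(x)), function(i) colnames(x)[x[i, ] > 0]),
      rownames(x)))
  }
  stop("x must be a story_vectors object or a named binary matrix")
}

#' Approximate nearest-neighbor candidates from the concept lattice
#'
#' Walks the concepts containing `doc` in decreasing order of term-set size,
#' emitting co-member documents (deduplicated, excluding `doc` itself) until
#' `m` candidates are collected or the concepts are exhausted. Documents that
#' co-occur in concepts with long term sets share many terms with the query,
#' so the walk yields an approximate nearest-neighbor list without ever
#' materializing the pairwise similarity graph.
#'
#' @param index a `concept_index`.
#' @param doc query doc_id.
#' @param m maximum number of candidates (`Inf` for the exhaustive pool).
#' @return character vector of candidate doc_ids (possibly shorter than `m`).
#' @export
candidate_neighbors <- function(index, doc, m) {
  stopifnot(inherits(index, "concept_index"))
  if (!is.infinite(m) && m < 1) stop("m must be >= 1")
  cis <- index$per_doc[[doc]]
  if (is.null(cis)) return(character(0))
  out <- character(0)
  for (ci in cis) {
    mem <- index$concepts[[ci]]$docs
    mem <- mem[mem != doc]
    new <- mem[!mem %in% out]
    if (length(new) > 0L) out <- c(out, new)
    if (length(out) >= m) return(out[seq_len(m)])
  }
  out
}
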