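# story evaluation and presentation: dispersion plots, MeSH labels, summaries

#' Dispersion plot and coefficient of a story
#'
#' Under the complementary-but-disjoint (CBD) view of discovery, an ideal
#' story connects its endpoints only through its consecutive links: when
#' non-adjacent documents of the story also satisfy the distance threshold,
#' the story "oversatisfies" it and is less interesting. The dispersion plot
#' records which non-adjacent pairs `(i, j)`, `j >= i + 2`, fall within
#' theta; the coefficient is
#' `eta = 1 - sum_filled (j - i - 1) / sum_all (j - i - 1)`,
#' a linear corner-heavy weighting so that a filled cell far from the
#' diagonal (a shortcut across many links) penalizes more than one near it.
#' eta is 1 when no non-adjacent pair is filled and 0 when all are; stories
#' with fewer than 3 documents have no non-adjacent pairs and score 1. The
#' plot evaluates the story's junctions only, never the evidence cliques.
#'
#' @param junctions character vector of story doc_ids (in order), or a
#'   `clique_chain`.
#' @param vectors a `story_vectors`.
#' @param theta distance threshold (defaults to the chain's own theta when a
#'   `clique_chain` is given).
#' @param weight optional weight function of `(i, j)` (0-based indices);
#'   defaults to the linear `j - i - 1`.
#' @return a `dispersion_plot`: `$n`, `$filled` (two-column matrix of 0-based
#'   index pairs), `$coefficient`.
#' @export
dispersion <- function(junctions, vectors, theta = NULL, weight = NULL) {
  if (inherits(junctions, "clique_chain")) {
    if (is.null(theta)) theta <- junctions$params$theta
    junctions <- junctions$junctions
  }
  if (is.null(theta)) stop("theta is required")
  n <- length(junctions)
  if (n < 2L) stop("a story needs at least two documents")
  if (is.null(weight)) weight <- function(i, j) j - i - 1
  dist <- .soergel_cache(vectors)
  filled <- matrix(integer(0), ncol = 2L,
                   dimnames = list(NULL, c("i", "j")))
  total_w <- 0
  filled_w <- 0
  if (n >= 3L) {
    for (i in 0:(n - 3L)) {
      for (j in (i + 2L):(n - 1L)) {
        w <- weight(i, j)
        total_w <- total_w + w
        if (dist(junctions[i + 1L], junctions[j + 1L]) <= theta) {
          filled <- rbind(filled, c(i, j))
          filled_w <- filled_w + w
        }
      }
    }
  }
  coefficient <- if (total_w == 0) 1 else 1 - filled_w / total_w
  structure(list(n = n, filled = filled, coefficient = coefficient,
                 theta = theta),
            class = "dispersion_plot")
}

#' @export
print.dispersion_plot <- function(x, ...) {
  cat("<dispersion_plot> n =", x$n, " filled cells =", nrow(x$filled),
      " coefficient =", round(x$coefficient, 4), "\n")
  invisible(x)
}

#' Write a dispersion plot as TSV
#'
#' 0/1 matrix over junction indices; only cells with `j >= i + 2` can be 1.
#'
#' @param plot a `dispersion_plot`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_tsv <- function(plot, path) {
  m <- matrix(0L, plot$n, plot$n)
  if (nrow(plot$filled) > 0L) {
    m[plot$filled + 1L] <- 1L
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Representative MeSH label for a document
#'
#' The document's MeSH term with the highest case-insensitive occurrence
#' count in its abstract; ties go to the lexicographically first term, and
#' when no term occurs at all the first listed term is used. Used to render
#' a chain as a readable sequence of concepts.
#'
#' @param doc a `story_document` with at least one MeSH term.
#' @return a single MeSH term.
#' @export
mesh_label <- function(doc) {
  if (length(doc$mesh_terms) == 0L) {
    stop("document has no MeSH terms: ", doc$doc_id)
  }
  abst <- tolower(.abstract_text(doc))
  counts <- vapply(doc$mesh_terms, function(tm) {
    m <- gregexpr(tolower(tm), abst, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  if (max(counts) == 0L) return(doc$mesh_terms[1L])
  hits <- doc$mesh_terms[counts == max(counts)]
  sort(hits)[1L]
}

#' Summarize a story as a sentence-tiled table
#'
#' One row per junction: its id, representative MeSH label, title, and the
#' sentence chosen by the cohesion filter's best entity-linked path. The
#' story must have passed [cohesion_filter()] first.
#'
#' @param chain a `clique_chain` (or character vector of junction doc_ids).
#' @param cohesion the passing result of [cohesion_filter()] for this story.
#' @param corpus the `story_corpus`.
#' @return data.frame with columns `doc_id`, `mesh_label`, `title`,
#'   `chosen_sentence`.
#' @export
summarize_story <- function(chain, cohesion, corpus) {
  junctions <- if (inherits(chain, "clique_chain")) chain$junctions else chain
  if (is.null(cohesion) || !isTRUE(cohesion$pass)) {
    stop("story has no cohesion path; run cohesion_filter first")
  }
  stopifnot(identical(cohesion$path$doc_id, junctions))
  rows <- lapply(seq_along(junctions), function(i) {
    doc <- corpus$documents[[junctions[i]]]
    data.frame(doc_id = doc$doc_id,
               mesh_label = mesh_label(doc),
               title = doc$title,
               chosen_sentence = doc$sentences[cohesion$path$position[i] + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
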