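#' Search parameters for story finding
#'
#' @param theta Soergel distance threshold in (0, 1): the maximum acceptable
#'   distance between neighboring documents of a story. Stricter (smaller)
#'   thresholds give longer but stronger stories.
#' @param k clique size >= 2: every link must be supported by a k-clique of
#'   documents all pairwise within `theta`; larger k demands more surrounding
#'   evidence.
#' @param b branching factor >= 1: number of candidate cliques returned per
#'   expansion.
#' @param max_expansions node budget for the A* search.
#' @return a `search_params` list.
#' @export
search_params <- function(theta = 0.90, k = 3L, b = 5L,
                          max_expansions = 100000L) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (k < 2L) stop("clique size k must be >= 2")
  if (b < 1L) stop("branching factor b must be >= 1")
  structure(list(theta = theta, k = as.integer(k), b = as.integer(b),
                 max_expansions = as.integer(max_expansions)),
            class = "search_params")
}

#' Minimum candidate count for clique generation
#'
#' The smallest m such that `choose(m, k - 1) >= b`: each clique is the
#' current junction plus k-1 of its m candidate neighbors, so m candidates
#' yield `choose(m, k - 1)` candidate cliques, equal to or slightly greater
#' than b but never less.
#'
#' @param k clique size (>= 2).
#' @param b branching factor (>= 1).
#' @return integer m.
#' @export
min_candidate_count <- function(k, b) {
  if (k < 2L) stop("k must be >= 2")
  if (b < 1L) stop("b must be >= 1")
  m <- k - 1L
  while (choose(m, k - 1L) < b) m <- m + 1L
  as.integer(m)
}

#' Generate successor cliques for a junction document
#'
#' Retrieves the top `m = min_candidate_count(k, b)` lattice candidates for
#' the junction, forms every (k-1)-subset, keeps the subsets for which the
#' junction plus subset is a valid clique (all pairwise Soergel distances at
#' most theta; candidate lists are approximate, so every pair is checked
#' explicitly), scores each clique by the mean distance from the junction to
#' the other members, and returns the best `b` as an ordered queue.
#'
#' @param junction doc_id of the current junction.
#' @param params a `search_params`.
#' @param index a `concept_index`.
#' @param vectors a `story_vectors`.
#' @param dist optional memoized distance function (internal use).
#' @return list of cliques, each `list(members, avg_distance)`, ordered by
#'   increasing `avg_distance`; empty when no valid clique exists (dead end).
#' @export
generate_successors <- function(junction, params, index, vectors,
                                dist = NULL) {
  stopifnot(inherits(params, "search_params"))
  if (is.null(dist)) dist <- .soergel_cache(vectors)
  m <- min_candidate_count(params$k, params$b)
  cands <- candidate_neighbors(index, junction, m)
  r <- params$k - 1L
  if (length(cands) < r) return(list())
  subsets <- utils::combn(cands, r, simplify = FALSE)
  cliques <- list()
  for (sub in subsets) {
    members <- c(junction, sub)
    ok <- TRUE
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq((i + 1L), length(members))) {
        if (dist(members[i], members[j]) > params$theta) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    avg <- mean(vapply(sub, function(d) dist(junction, d), numeric(1)))
    cliques[[length(cliques) + 1L]] <- list(members = members,
                                            avg_distance = avg)
  }
  if (length(cliques) == 0L) return(list())
  keys <- vapply(cliques, function(cl) paste(sort(cl$members), collapse = " "),
                 character(1))
  avgs <- vapply(cliques, `[[`, numeric(1), "avg_distance")
  ord <- order(avgs, keys)
  cliques[ord][seq_len(min(params$b, length(cliques)))]
}

#' A* search for a story between two documents
#'
#' Best-first search minimizing `f = g + h`, where `g` is the cumulative
#' Soergel distance over consecutive junctions and the heuristic `h(d)` is
#' the straight-line Soergel distance from d to the end document. Because the
#' Soergel distance obeys the triangle inequality, h never overestimates the
#' remaining path cost, so the search returns the minimum-cost clique chain
#' reachable under the branching-factor-constrained successor structure.
#' Every non-junction member of an expanded clique is enqueued as a candidate
#' next junction carrying its supporting clique; junctions never repeat
#' within a chain.
#'
#' @param start,end doc_ids (must differ; both vectors must be non-empty).
#' @param params a `search_params`.
#' @param index a `concept_index`.
#' @param vectors a `story_vectors`.
#' @param dist optional memoized distance function (internal use).
#' @return a `clique_chain` (junctions, per-link evidence cliques, link
#'   distances, total cost) or NULL when no story exists within the budget.
#' @export
astar_story <- function(start, end, params, index, vectors, dist = NULL) {
  stopifnot(inherits(params, "search_params"))
  if (identical(start, end)) stop("start and end documents must differ")
  for (id in c(start, end)) {
    v <- vectors$vectors[[id]]
    if (is.null(v)) stop("document not in vectors: ", id)
    if (length(v) == 0L) stop("document has an empty term vector: ", id)
  }
  if (is.null(dist)) dist <- .soergel_cache(vectors)

  # frontier entries: doc, g, f, junctions (path), cliques, link_dists
  frontier <- list(list(doc = start, g = 0,
                        f = dist(start, end), h = dist(start, end),
                        junctions = start, cliques = list(),
                        link_dists = numeric(0)))
  closed <- character(0)
  expansions <- 0L

  while (length(frontier) > 0L) {
    fs <- vapply(frontier, `[[`, numeric(1), "f")
    hs <- vapply(frontier, `[[`, numeric(1), "h")
    ids <- vapply(frontier, `[[`, character(1), "doc")
    best <- order(fs, hs, ids)[1]
    node <- frontier[[best]]
    frontier[[best]] <- NULL

    if (node$doc %in% closed) next
    closed <- c(closed, node$doc)

    if (node$doc == end) {
      return(structure(list(
        junctions = node$junctions,
        cliques = node$cliques,
        link_distances = node$link_dists,
        total_cost = node$g,
        params = params
      ), class = "clique_chain"))
    }

    expansions <- expansions + 1L
    if (expansions > params$max_expansions) return(NULL)

    for (cl in generate_successors(node$doc, params, index, vectors, dist)) {
      for (mem in setdiff(cl$members, node$doc)) {
        if (mem %in% node$junctions || mem %in% closed) next
        step <- dist(node$doc, mem)
        g2 <- node$g + step
        h2 <- dist(mem, end)
        frontier[[length(frontier) + 1L]] <- list(
          doc = mem, g = g2, f = g2 + h2, h = h2,
          junctions = c(node$junctions, mem),
          cliques = c(node$cliques, list(cl)),
          link_dists = c(node$link_dists, step)
        )
      }
    }
  }
  NULL
}

#' @export
print.clique_chain <- function(x, ...) {
  cat("<clique_chain> ", paste(x$junctions, collapse = " -> "),
      "\n  links: ", length(x$link_distances),
      "  total cost: ", round(x$total_cost, 4),
      "  (theta = ", x$params$theta, ", k = ", x$params$k, ")\n", sep = "")
  invisible(x)
}

#' Validate the invariants of a clique chain
#'
#' Re-checks, from the vectors alone, that every link distance is within
#' theta, consecutive junctions co-occur in that link's clique, all pairwise
#' clique-member distances are within theta, and the total cost equals the
#' sum of link distances.
#'
#' @param chain a `clique_chain`.
#' @param vectors the `story_vectors` it was searched over.
#' @return TRUE, or a character vector describing the violated invariants.
#' @export
validate_chain <- function(chain, vectors) {
  stopifnot(inherits(chain, "clique_chain"))
  dist <- .soergel_cache(vectors)
  th <- chain$params$theta
  bad <- character(0)
  n <- length(chain$junctions)
  if (anyDuplicated(chain$junctions)) bad <- c(bad, "repeated junction")
  for (i in seq_len(n - 1L)) {
    a <- chain$junctions[i]; b <- chain$junctions[i + 1L]
    if (dist(a, b) > th + 1e-12) bad <- c(bad, paste("link over theta:", a, b))
    cl <- chain$cliques[[i]]
    if (!all(c(a, b) %in% cl$members)) {
      bad <- c(bad, paste("junctions not in clique at link", i))
    }
    if (length(cl$members) != chain$params$k) {
      bad <- c(bad, paste("clique size mismatch at link", i))
    }
    pairs <- utils::combn(cl$members, 2L, simplify = FALSE)
    for (p in pairs) {
      if (dist(p[1], p[2]) > th + 1e-12) {
        bad <- c(bad, paste("clique pair over theta at link", i))
        break
      }
    }
  }
  if (abs(sum(chain$link_distances) - chain$total_cost) > 1e-9) {
    bad <- c(bad, "total cost does not equal sum of link distances")
  }
  if (length(bad) == 0L) TRUE else bad
}
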