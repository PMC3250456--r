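# vectors engineered so that D(A,B) = D(B,C) = D(C,D) = 0.8 exactly and all
# other pairs are disjoint (distance 1)
chain_vectors <- function() {
  as_vectors(list(
    A = c(x = 1),
    B = c(x = 0.4, y = 1),
    C = c(y = 1, z = 3.6),
    D = c(z = 3.6, w = 13.4)
  ))
}

chain_index <- function(vecs) {
  ids <- names(vecs$vectors)
  terms <- sort(unique(unlist(lapply(vecs$vectors, names))))
  mat <- matrix(0L, length(ids), length(terms),
                dimnames = list(ids, terms))
  for (id in ids) mat[id, names(vecs$vectors[[id]])] <- 1L
  mine_concepts(mat, min_support = 1 / length(ids))
}

test_that("minimum candidate count solves choose(m, k-1) >= b tightly", {
  expect_equal(min_candidate_count(2, 1), 1L)
  expect_equal(min_candidate_count(3, 10), 5L)
  expect_equal(min_candidate_count(3, 3), 3L)
  for (k in 2:5) {
    for (b in c(1, 2, 5, 10, 50)) {
      m <- min_candidate_count(k, b)
      expect_gte(choose(m, k - 1), b)
      if (m > k - 1) expect_lt(choose(m - 1, k - 1), b)
    }
  }
})

test_that("successor generation checks every pairwise distance", {
  # three mutually close candidates around a junction
  vecs <- as_vectors(list(
    J = c(t1 = 1, t2 = 1, t3 = 1),
    a = c(t1 = 1, t2 = 1, t4 = 1),
    b = c(t1 = 1, t3 = 1, t5 = 1),
    c = c(t2 = 1, t3 = 1, t6 = 1)
  ))
  idx <- chain_index(vecs)
  p <- search_params(theta = 0.85, k = 3L, b = 3L)
  succ <- generate_successors("J", p, idx, vecs)
  expect_length(succ, 3L)
  # ordered by average junction distance
  avgs <- vapply(succ, `[[`, numeric(1), "avg_distance")
  expect_true(all(diff(avgs) >= 0))
  for (cl in succ) {
    expect_length(cl$members, 3L)
    expect_true("J" %in% cl$members)
    pairs <- utils::combn(cl$members, 2, simplify = FALSE)
    for (pr in pairs) {
      expect_lte(soergel_distance(vecs$vectors[[pr[1]]],
                                  vecs$vectors[[pr[2]]]), p$theta)
    }
  }
  # candidates close to the junction but mutually disjoint cannot form a
  # 3-clique
  vecs2 <- as_vectors(list(
    J = c(t1 = 1, t2 = 1, t3 = 1),
    a = c(t1 = 1, u1 = 0.2),
    b = c(t2 = 1, u2 = 0.2),
    c = c(t3 = 1, u3 = 0.2)
  ))
  idx2 <- chain_index(vecs2)
  expect_length(generate_successors("J", search_params(0.9, 3L, 3L), idx2,
                                    vecs2), 0L)
  # for k = 2 each in-threshold candidate is its own clique
  succ2 <- generate_successors("J", search_params(0.9, 2L, 3L), idx2, vecs2)
  expect_length(succ2, 3L)
  expect_true(all(lengths(lapply(succ2, `[[`, "members")) == 2L))
})

test_that("A* recovers the optimal chain on the worked 4-document corpus", {
  vecs <- chain_vectors()
  idx <- chain_index(vecs)
  p <- search_params(theta = 0.85, k = 2L, b = 2L)
  chain <- astar_story("A", "D", p, idx, vecs)
  expect_s3_class(chain, "clique_chain")
  expect_equal(chain$junctions, c("A", "B", "C", "D"))
  expect_equal(chain$total_cost, 2.4, tolerance = 1e-9)
  expect_equal(chain$link_distances, rep(0.8, 3), tolerance = 1e-9)
  expect_true(isTRUE(validate_chain(chain, vecs)))

  # theta below every inter-document distance -> no story
  expect_null(astar_story("A", "D", search_params(0.5, 2L, 2L), idx, vecs))
  # immediate goal for adjacent endpoints
  short <- astar_story("A", "B", p, idx, vecs)
  expect_equal(short$junctions, c("A", "B"))
  expect_length(short$cliques, 1L)
  # argument errors
  expect_error(astar_story("A", "A", p, idx, vecs), "differ")
  vecs_empty <- vecs
  vecs_empty$vectors$A <- stats::setNames(numeric(0), character(0))
  expect_error(astar_story("A", "D", p, idx, vecs_empty), "empty")
})

test_that("A* cost equals exhaustive constrained-optimal cost", {
  set.seed(97)
  for (rep in 1:12) {
    vecs <- random_sparse_vectors(sample(8:14, 1), n_terms = 20L,
                                  min_k = 4L, max_k = 7L)
    ids <- names(vecs$vectors)
    mat <- matrix(0L, length(ids),
                  length(unique(unlist(lapply(vecs$vectors, names)))))
    terms <- sort(unique(unlist(lapply(vecs$vectors, names))))
    dimnames(mat) <- list(ids, terms)
    for (id in ids) mat[id, names(vecs$vectors[[id]])] <- 1L
    idx <- mine_concepts(mat, min_support = 1 / length(ids))
    p <- search_params(theta = sample(c(0.9, 0.95), 1),
                       k = sample(2:3, 1), b = 3L)
    se <- sample(ids, 2L)
    got <- astar_story(se[1], se[2], p, idx, vecs)
    want <- oracle_optimal_cost(se[1], se[2], p, idx, vecs)
    if (is.null(got)) {
      expect_true(is.infinite(want))
    } else {
      expect_equal(got$total_cost, want, tolerance = 1e-9)
    }
  }
})

test_that("the pairwise similarity graph is never materialized", {
  # the distance cache only ever holds pairs the search actually touched:
  # far fewer than n^2 on a corpus where the story is a short hop
  sim <- generate_corpus(synthesis_params())
  corpus <- sim$corpus
  corpus$documents <- Filter(function(d) !review_filter(d), corpus$documents)
  vecs <- build_vectors(corpus)
  idx <- mine_concepts(vecs)
  dist <- storyline:::.soergel_cache(vecs)
  p <- search_params(theta = sim$ground_truth$theta_star, k = 2L, b = 5L)
  chain <- astar_story("B1", "B3", p, idx, vecs, dist = dist)
  expect_s3_class(chain, "clique_chain")
  n <- length(vecs$vectors)
  touched <- length(ls(environment(dist)$memo))
  expect_lt(touched, n * (n - 1) / 2)
})
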