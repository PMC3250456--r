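#' Monte-Carlo p-value for a junction clique
#'
#' Estimates how surprising it is that the junction participates in a valid
#' k-clique: repeatedly draws k-1 documents uniformly at random from the
#' candidate pool and checks whether all edges of the formed k-clique (among
#' the sampled documents and with the junction) satisfy the distance
#' threshold. The p-value is the success fraction, floored at 1/R so that R
#' iterations bound the smallest detectable p-value.
#'
#' @param junction doc_id of the junction.
#' @param pool character vector of candidate doc_ids (the pool the observed
#'   clique was drawn from); must have at least k-1 members.
#' @param k clique size.
#' @param theta distance threshold.
#' @param vectors a `story_vectors`.
#' @param R number of Monte-Carlo iterations (default 50000).
#' @param rng_seed integer seed; identical seeds give identical p-values.
#' @return p-value in `[1/R, 1]`.
#' @export
junction_p_value <- function(junction, pool, k, theta, vectors,
                             R = 50000L, rng_seed = 1L) {
  pool <- setdiff(unique(pool), junction)
  if (length(pool) < k - 1L) {
    stop("candidate pool smaller than k - 1 (", length(pool), " < ", k - 1L, ")")
  }
  if (R < 1L) stop("R must be >= 1")
  dist <- .soergel_cache(vectors)
  # validity structure: edges to the junction and among pool members
  ok_j <- vapply(pool, function(d) dist(junction, d) <= theta, logical(1))
  npool <- length(pool)
  ok_p <- matrix(TRUE, npool, npool)
  if (k > 2L) {
    for (i in seq_len(npool - 1L)) {
      for (j in seq((i + 1L), npool)) {
        ok <- dist(pool[i], pool[j]) <= theta
        ok_p[i, j] <- ok; ok_p[j, i] <- ok
      }
    }
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(rng_seed))
  successes <- 0L
  r <- k - 1L
  for (it in seq_len(R)) {
    idx <- sample.int(npool, r)
    if (all(ok_j[idx]) && all(ok_p[idx, idx])) successes <- successes + 1L
  }
  max(successes, 1L) / R
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Chain-level p-value
#'
#' The overall p-value of a clique chain is the product of the per-junction
#' clique p-values.
#'
#' @param junction_ps numeric vector of per-junction p-values in (0, 1].
#' @return product of the inputs.
#' @export
chain_p_value <- function(junction_ps) {
  if (length(junction_ps) == 0L) stop("empty p-value list")
  if (any(junction_ps <= 0 | junction_ps > 1)) {
    stop("junction p-values must lie in (0, 1]")
  }
  prod(junction_ps)
}

#' FDR q-values for a batch of chain p-values
#'
#' Benjamini-Hochberg adjusted values (with the usual step-up monotonicity
#' enforcement), order-aligned with the input. A Storey-type estimate with a
#' fixed lambda of 0.5 is available via `method = "storey"`.
#'
#' @param chain_ps numeric vector of p-values in (0, 1].
#' @param method `"BH"` (default) or `"storey"`.
#' @return numeric vector of q-values, same order as input.
#' @export
q_values <- function(chain_ps, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(chain_ps) == 0L) stop("empty p-value list")
  q <- stats::p.adjust(chain_ps, method = "BH")
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(chain_ps > lambda) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Significance of a clique chain
#'
#' Computes one Monte-Carlo p-value per link of the chain (pooling, for each
#' junction, its concept-lattice candidates) and the chain-level product.
#'
#' @param chain a `clique_chain`.
#' @param index a `concept_index`.
#' @param vectors a `story_vectors`.
#' @param R Monte-Carlo iterations per junction.
#' @param rng_seed integer seed.
#' @param pool `"lattice"` (default: the junction's exhaustive candidate
#'   list from the concept lattice), `"top-m"` (only the m candidates the
#'   search itself retrieves) or `"corpus"` (every other document).
#' @return list with `junction_p`, `chain_p`, `q_value` (NA until assigned
#'   over a batch) and `iterations`.
#' @export
chain_significance <- function(chain, index, vectors, R = 50000L,
                               rng_seed = 1L,
                               pool = c("lattice", "top-m", "corpus")) {
  stopifnot(inherits(chain, "clique_chain"))
  pool <- match.arg(pool)
  k <- chain$params$k
  n <- length(chain$junctions)
  ps <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    junction <- chain$junctions[i]
    cand <- switch(pool,
      "lattice" = candidate_neighbors(index, junction, Inf),
      "top-m" = candidate_neighbors(
        index, junction, min_candidate_count(k, chain$params$b)),
      "corpus" = setdiff(names(vectors$vectors), junction)
    )
    # the observed clique came from this pool; make sure it is inside so the
    # test is well-defined even for tiny candidate lists
    cand <- union(cand, setdiff(chain$cliques[[i]]$members, junction))
    ps[i] <- junction_p_value(junction, cand, k, chain$params$theta,
                              vectors, R = R,
                              rng_seed = rng_seed + i - 1L)
  }
  list(junction_p = ps, chain_p = chain_p_value(ps), q_value = NA_real_,
       iterations = as.integer(R))
}

#' Filter chains by statistical significance
#'
#' Keeps the chains whose chain-level p-value and q-value are at or below
#' the given thresholds; order is preserved. Chains must carry a
#' `$significance` element with `chain_p` and `q_value` filled in.
#'
#' @param chains list of chains with significance results attached.
#' @param p_max,q_max thresholds in (0, 1].
#' @return the surviving sub-list.
#' @export
significance_filter <- function(chains, p_max = 0.001, q_max = 0.05) {
  if (p_max <= 0 || p_max > 1 || q_max <= 0 || q_max > 1) {
    stop("thresholds must be in (0, 1]")
  }
  keep <- vapply(chains, function(ch) {
    sig <- ch$significance
    !is.null(sig) && sig$chain_p <= p_max &&
      (is.na(sig$q_value) || sig$q_value <= q_max)
  }, logical(1))
  chains[keep]
}
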