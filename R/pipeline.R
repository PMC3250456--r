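# end-to-end orchestration: ingest -> vectors -> index -> search ->
# significance -> context filter -> cohesion filter -> report

#' Pipeline configuration
#'
#' Collects every module parameter in one declarative list so that a run is
#' fully reproducible from its config. Any field can be overridden.
#'
#' @param theta,k,b,max_expansions search parameters (see [search_params()]).
#' @param min_support concept-lattice minimum support (NULL = about 2
#'   documents of expected support).
#' @param R Monte-Carlo iterations per junction.
#' @param sig_seed seed for the significance test.
#' @param sig_pool candidate pool for significance: "lattice", "top-m" or
#'   "corpus".
#' @param p_max,q_max significance thresholds.
#' @param j_min context-overlap Jaccard threshold.
#' @param cap seed-label cap per label.
#' @param max_pairs optional cap on the number of seed pairs searched
#'   (Inf = all).
#' @param q_method "BH" or "storey".
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(theta = 0.90, k = 3L, b = 5L,
                            max_expansions = 100000L, min_support = NULL,
                            R = 50000L, sig_seed = 1L,
                            sig_pool = "lattice",
                            p_max = 0.001, q_max = 0.05, j_min = 0.05,
                            cap = 700L, max_pairs = Inf, q_method = "BH") {
  structure(list(theta = theta, k = as.integer(k), b = as.integer(b),
                 max_expansions = as.integer(max_expansions),
                 min_support = min_support, R = as.integer(R),
                 sig_seed = as.integer(sig_seed), sig_pool = sig_pool,
                 p_max = p_max, q_max = q_max, j_min = j_min,
                 cap = as.integer(cap), max_pairs = max_pairs,
                 q_method = q_method),
            class = "pipeline_config")
}

#' Run the storytelling pipeline end to end
#'
#' Prunes reviews, models the documents, mines the concept lattice, labels
#' seeds and forms term-disjoint start-end pairs, searches a clique chain
#' per pair, then applies the significance, context-overlap and
#' sentence-cohesion filters in order and summarizes the survivors. The
#' stage counts are reported in pipeline order (after search, after p/q
#' filtering, after context filtering, after cohesion filtering) and are
#' non-increasing by construction.
#'
#' @param corpus a `story_corpus` (reviews are pruned here if present).
#' @param seed_keywords named list label -> keyword vector for seed labeling.
#' @param start_labels,end_labels which labels mark starts and ends.
#' @param gazetteer entity names for the cohesion filter.
#' @param training_sentences labeled sentence data.frame for the classifier
#'   (or an already trained `sentence_nb` via `model`).
#' @param config a `pipeline_config`.
#' @param model optional pre-trained `sentence_nb`.
#' @param stopwords stopword list.
#' @param phrase_lexicon indicator-phrase lexicon for classifier training.
#' @param verbose emit per-stage progress to stderr.
#' @return a `story_run`: `$stories` (each with chain, significance, filter
#'   results, dispersion and summary), `$stage_counts`, `$config`.
#' @export
run_pipeline <- function(corpus, seed_keywords, start_labels, end_labels,
                         gazetteer, training_sentences = NULL,
                         config = pipeline_config(), model = NULL,
                         stopwords = default_stopwords(),
                         phrase_lexicon = default_phrase_lexicon(),
                         verbose = FALSE) {
  stopifnot(inherits(corpus, "story_corpus"),
            inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[storyline] ", ...)

  # initial pruning: review papers out
  n0 <- length(corpus$documents)
  corpus$documents <- Filter(function(d) !review_filter(d), corpus$documents)
  corpus$provenance$dropped$review <-
    (corpus$provenance$dropped$review %||% 0L) + n0 - length(corpus$documents)
  say("pruned ", n0 - length(corpus$documents), " review documents, ",
      length(corpus$documents), " remain")

  vectors <- build_vectors(corpus, stopwords)
  index <- mine_concepts(vectors, config$min_support)
  say("lattice: ", length(index$concepts), " concepts")

  corpus <- label_seeds(corpus, seed_keywords, cap = config$cap)
  pairs <- make_seed_pairs(corpus, start_labels, end_labels, vectors)
  if (nrow(pairs) > config$max_pairs) {
    pairs <- pairs[seq_len(config$max_pairs), , drop = FALSE]
  }
  say(nrow(pairs), " term-disjoint seed pairs")

  params <- search_params(theta = config$theta, k = config$k, b = config$b,
                          max_expansions = config$max_expansions)
  dist <- .soergel_cache(vectors)
  stories <- list()
  for (r in seq_len(nrow(pairs))) {
    chain <- astar_story(pairs$start_id[r], pairs$end_id[r], params, index,
                         vectors, dist = dist)
    if (!is.null(chain)) {
      stories[[length(stories) + 1L]] <- list(chain = chain)
    }
  }
  n_search <- length(stories)
  say("A* search: ", n_search, " stories")

  # significance: per-chain Monte-Carlo p, batch q
  for (i in seq_along(stories)) {
    stories[[i]]$significance <- chain_significance(
      stories[[i]]$chain, index, vectors, R = config$R,
      rng_seed = config$sig_seed + i - 1L, pool = config$sig_pool)
  }
  if (length(stories) > 0L) {
    qs <- q_values(vapply(stories, function(s) s$significance$chain_p,
                          numeric(1)), method = config$q_method)
    for (i in seq_along(stories)) stories[[i]]$significance$q_value <- qs[i]
  }
  keep <- vapply(stories, function(s) {
    s$significance$chain_p <= config$p_max &&
      s$significance$q_value <= config$q_max
  }, logical(1))
  stories <- stories[keep]
  n_sig <- length(stories)
  say("significance filter: ", n_sig, " stories")

  if (is.null(model)) {
    if (is.null(training_sentences)) {
      stop("either a trained model or training_sentences is required")
    }
    model <- train_classifier(training_sentences, phrase_lexicon)
  }
  keep <- logical(length(stories))
  for (i in seq_along(stories)) {
    ctx <- context_overlap_filter(stories[[i]]$chain, corpus, model,
                                  j_min = config$j_min,
                                  stopwords = stopwords)
    stories[[i]]$context <- ctx
    keep[i] <- ctx$pass
  }
  stories <- stories[keep]
  n_ctx <- length(stories)
  say("context filter: ", n_ctx, " stories")

  if (length(stories) > 0L) {
    ann <- annotate_entities(corpus, gazetteer)
    keep <- logical(length(stories))
    for (i in seq_along(stories)) {
      coh <- cohesion_filter(stories[[i]]$chain, ann)
      stories[[i]]$cohesion <- coh
      keep[i] <- coh$pass
    }
    stories <- stories[keep]
  }
  n_coh <- length(stories)
  say("cohesion filter: ", n_coh, " stories")

  for (i in seq_along(stories)) {
    stories[[i]]$dispersion <- dispersion(stories[[i]]$chain, vectors)
    stories[[i]]$summary <- summarize_story(stories[[i]]$chain,
                                            stories[[i]]$cohesion, corpus)
  }

  structure(list(
    stories = stories,
    stage_counts = c(after_search = n_search,
                     after_significance = n_sig,
                     after_context = n_ctx,
                     after_cohesion = n_coh),
    config = config,
    n_pairs = nrow(pairs)
  ), class = "story_run")
}

#' @export
print.story_run <- function(x, ...) {
  cat("<story_run> stage counts:\n")
  print(x$stage_counts)
  for (s in x$stories) {
    cat("  ", paste(s$chain$junctions, collapse = " -> "),
        " (p = ", signif(s$significance$chain_p, 3),
        ", eta = ", round(s$dispersion$coefficient, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Serialize a story (with its evidence) to JSON
#'
#' @param story one element of a `story_run`'s `$stories`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_story_json <- function(story, path) {
  out <- list(
    junctions = story$chain$junctions,
    link_distances = story$chain$link_distances,
    total_cost = story$chain$total_cost,
    cliques = lapply(story$chain$cliques, function(cl) {
      list(members = cl$members, avg_distance = cl$avg_distance)
    }),
    significance = story$significance,
    context_scores = story$context$link_scores,
    cohesion = if (!is.null(story$cohesion$path)) {
      list(positions = story$cohesion$path$position,
           score = story$cohesion$score)
    },
    dispersion = story$dispersion$coefficient
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
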