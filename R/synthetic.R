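# deterministic synthetic corpora with planted story structure
#
# The generator emits two kinds of documents over disjoint integer-token
# vocabularies: (a) topic clusters of mutually similar documents, and (b) a
# planted "bridge" chain in which adjacent documents share a controlled
# fraction of their vocabulary and non-adjacent ones share essentially none
# (the complementary-but-disjoint shape). Template filler words are either
# stopwords or indicator-phrase words present in every document (so they get
# zero idf weight and drop out of the vector model), which keeps the Soergel
# distances analytically controllable.

#' Parameters for synthetic corpus generation
#'
#' @param n_clusters number of background topic clusters.
#' @param docs_per_cluster documents per cluster.
#' @param vocab_per_cluster topic terms per cluster pool.
#' @param shared_vocab size of the weak shared pool that loosely connects
#'   all documents (each document draws each shared term with probability
#'   0.8, so the pool never reaches full document frequency).
#' @param chain_length number of planted bridge documents (story junctions).
#' @param chain_overlap fraction of a bridge document's topic vocabulary
#'   shared with each adjacent bridge document; must be below 0.5 so
#'   interior documents keep unique terms (0 plants a broken chain that
#'   yields no story).
#' @param sentences_per_doc abstract sentences per document.
#' @param context_fraction fraction of sentences that are context sentences.
#' @param gazetteer_size number of synthetic named entities.
#' @param review_fraction fraction of cluster documents flagged as reviews.
#' @param evidence_per_link number of planted evidence documents per bridge
#'   link; they share most of the link pool with both junctions, so cliques
#'   of size 3 and above have support at loose thresholds (when
#'   `chain_overlap` is 0 the link pools are empty and the evidence
#'   documents detach from the bridge).
#' @param rng_seed integer seed; generation is a pure function of the
#'   parameters.
#' @return a `synthesis_params` list.
#' @export
synthesis_params <- function(n_clusters = 2L, docs_per_cluster = 12L,
                             vocab_per_cluster = 30L, shared_vocab = 6L,
                             chain_length = 5L, chain_overlap = 0.4,
                             sentences_per_doc = 6L, context_fraction = 0.5,
                             gazetteer_size = 16L, review_fraction = 0.15,
                             evidence_per_link = 2L, rng_seed = 42L) {
  p <- list(n_clusters = as.integer(n_clusters),
            docs_per_cluster = as.integer(docs_per_cluster),
            vocab_per_cluster = as.integer(vocab_per_cluster),
            shared_vocab = as.integer(shared_vocab),
            chain_length = as.integer(chain_length),
            chain_overlap = chain_overlap,
            sentences_per_doc = as.integer(sentences_per_doc),
            context_fraction = context_fraction,
            gazetteer_size = as.integer(gazetteer_size),
            review_fraction = review_fraction,
            evidence_per_link = as.integer(evidence_per_link),
            rng_seed = as.integer(rng_seed))
  if (p$chain_length < 2L) stop("chain_length must be >= 2")
  if (p$chain_overlap < 0 || p$chain_overlap >= 0.5) {
    stop("chain_overlap must be in [0, 0.5): interior bridge documents ",
         "need unique vocabulary beyond the two shared pools")
  }
  if (p$context_fraction <= 0 || p$context_fraction > 1) {
    stop("context_fraction must be in (0, 1]")
  }
  if (p$gazetteer_size < p$chain_length - 1L) {
    stop("gazetteer_size must cover the ", p$chain_length - 1L,
         " bridge links")
  }
  if (any(unlist(p[c("n_clusters", "docs_per_cluster", "vocab_per_cluster",
                     "shared_vocab", "sentences_per_doc")]) < 1L)) {
    stop("all counts must be >= 1")
  }
  structure(p, class = "synthesis_params")
}

# topic terms per bridge document
.BRIDGE_TERMS <- 20L

.ctx_phrases <- c("investigated", "study", "known to")
.res_phrases <- c("observed", "showed", "significant change", "evident",
                  "identified")

.ctx_sentence <- function(terms, entity = NULL) {
  paste0("In this study we investigated ",
         paste(c(terms, entity), collapse = " "), ".")
}

.res_sentence <- function(terms) {
  paste0("We observed a significant change in ",
         paste(terms, collapse = " "),
         " and this showed that it was evident.")
}

#' Generate a synthetic corpus with a planted story
#'
#' Emits topic clusters plus a planted bridge chain whose adjacent documents
#' satisfy a Soergel threshold `theta_star` (computed from the generated
#' vectors and reported in the ground truth) while non-adjacent bridge pairs
#' and bridge/cluster pairs do not; early sentences use context-indicator
#' phrases and late sentences result-indicator phrases; synthetic gazetteer
#' entities are threaded along the bridge so exactly one cohesive sentence
#' path is guaranteed to exist; a fraction of cluster documents is flagged
#' as reviews. The planted chain endpoints carry seed keywords in their
#' titles and have disjoint modeled term sets.
#'
#' @param params a `synthesis_params`.
#' @return list with `corpus` (a `story_corpus`, reviews included — the
#'   pipeline's ingestion prunes them), `ground_truth` (junction ids,
#'   `theta_star`, seed keywords/labels, entity path, review ids, sentence
#'   labels), `gazetteer` (entity names) and `params`.
#' @export
generate_corpus <- function(params = synthesis_params()) {
  stopifnot(inherits(params, "synthesis_params"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(params$rng_seed)

  L <- params$chain_length
  t_terms <- .BRIDGE_TERMS
  s_size <- round(params$chain_overlap * t_terms)
  if (L > 2L && t_terms - 2L * s_size < 1L) {
    stop("chain_overlap leaves interior bridge documents without unique ",
         "vocabulary (", t_terms, " terms, ", s_size, " shared per link)")
  }

  term_counter <- 0L
  new_terms <- function(n, tag) {
    out <- sprintf("%s%04dx", tag, term_counter + seq_len(n))
    term_counter <<- term_counter + n
    out
  }

  shared_pool <- new_terms(params$shared_vocab, "shr")
  link_pools <- lapply(seq_len(L - 1L), function(i) new_terms(s_size, "brl"))
  unique_pools <- lapply(seq_len(L), function(i) {
    n_shared <- s_size * ((i > 1L) + (i < L))
    new_terms(t_terms - n_shared, "bru")
  })
  cluster_pools <- lapply(seq_len(params$n_clusters), function(c) {
    new_terms(params$vocab_per_cluster, "clu")
  })

  # entities: one per bridge link, remainder for the clusters
  gaz <- sprintf("NPQ%02dX", seq_len(params$gazetteer_size))
  bridge_ents <- gaz[seq_len(L - 1L)]
  cluster_ents <- gaz[-seq_len(L - 1L)]
  if (length(cluster_ents) == 0L) cluster_ents <- gaz

  kw_start <- "alphastoryin"
  kw_end <- "omegastoryout"

  n_ctx <- max(1L, min(params$sentences_per_doc,
                       ceiling(params$context_fraction *
                               params$sentences_per_doc)))
  n_res <- params$sentences_per_doc - n_ctx

  make_doc <- function(doc_id, terms, entities, title_extra = NULL,
                       review = FALSE) {
    # jitter term frequencies so distances vary document to document
    freq <- 1L + stats::rbinom(length(terms), 1L, 0.3)
    bag <- rep(terms, freq)
    bag <- sample(bag)
    cuts <- sort(c(0, length(bag),
                   if (params$sentences_per_doc > 1L)
                     sample(seq_len(max(1L, length(bag) - 1L)),
                            params$sentences_per_doc - 1L, replace = TRUE)))
    groups <- lapply(seq_len(params$sentences_per_doc), function(i) {
      if (cuts[i] >= cuts[i + 1L]) character(0)
      else bag[(cuts[i] + 1L):cuts[i + 1L]]
    })
    sents <- character(params$sentences_per_doc)
    for (i in seq_len(params$sentences_per_doc)) {
      g <- if (length(groups[[i]]) == 0L) terms[1L] else groups[[i]]
      if (i <= n_ctx) {
        ent <- if (i == 1L) entities else NULL
        sents[i] <- .ctx_sentence(g, ent)
      } else {
        sents[i] <- .res_sentence(g)
      }
    }
    if (review) {
      sents <- c(sents, "This review surveys the area.")
    }
    title <- paste(c("On", terms[seq_len(min(2L, length(terms)))],
                     title_extra), collapse = " ")
    story_document(doc_id, title, sents,
                   mesh_terms = terms[seq_len(min(2L, length(terms)))],
                   publication_types = if (review) "Review"
                                       else "Journal Article")
  }

  docs <- list()
  bridge_ids <- sprintf("B%d", seq_len(L))
  # the planted endpoints must have disjoint modeled term sets (they become
  # the seed pair), so they draw from disjoint halves of the shared pool;
  # everyone else samples the whole pool
  half <- max(1L, params$shared_vocab %/% 2L)
  shared_for <- function(i) {
    if (i == 1L) shared_pool[seq_len(half)]
    else if (i == L) shared_pool[seq((half + 1L), params$shared_vocab)]
    else shared_pool[stats::runif(params$shared_vocab) < 0.8]
  }
  for (i in seq_len(L)) {
    terms <- c(unique_pools[[i]],
               if (i > 1L) link_pools[[i - 1L]],
               if (i < L) link_pools[[i]],
               shared_for(i))
    ents <- c(if (i > 1L) bridge_ents[i - 1L],
              if (i < L) bridge_ents[i])
    extra <- if (i == 1L) kw_start else if (i == L) kw_end else NULL
    docs[[length(docs) + 1L]] <-
      make_doc(bridge_ids[i], terms, ents, title_extra = extra)
  }

  # evidence documents supporting each link: mostly link-pool vocabulary,
  # so they sit near both junctions of their link (and near each other)
  # without shortcutting non-adjacent junctions
  evidence_ids <- character(0)
  if (params$evidence_per_link > 0L && L > 1L) {
    for (i in seq_len(L - 1L)) {
      for (e in seq_len(params$evidence_per_link)) {
        id <- sprintf("E%d_%d", i, e)
        evidence_ids <- c(evidence_ids, id)
        terms <- c(
          if (s_size > 0L) sample(link_pools[[i]],
                                  ceiling(0.75 * s_size)),
          new_terms(4L, "evu"),
          shared_pool[stats::runif(params$shared_vocab) < 0.8])
        docs[[length(docs) + 1L]] <-
          make_doc(id, terms, bridge_ents[i])
      }
    }
  }

  review_ids <- character(0)
  n_rev <- round(params$review_fraction * params$docs_per_cluster)
  for (c in seq_len(params$n_clusters)) {
    for (d in seq_len(params$docs_per_cluster)) {
      id <- sprintf("C%dD%02d", c, d)
      terms <- c(sample(cluster_pools[[c]],
                        min(12L, params$vocab_per_cluster)),
                 shared_pool[stats::runif(params$shared_vocab) < 0.8])
      ents <- sample(cluster_ents, 1L)
      review <- d <= n_rev
      if (review) review_ids <- c(review_ids, id)
      docs[[length(docs) + 1L]] <- make_doc(id, terms, ents, review = review)
    }
  }

  corpus <- .new_corpus(docs, provenance = list(
    source = "synthetic", n_input = length(docs),
    dropped = list(missing_fields = 0L, review = 0L)
  ))

  # derive theta_star from the distances of the pruned, modeled corpus,
  # exactly as the pipeline will see it
  kept <- corpus
  kept$documents <- Filter(function(d) !review_filter(d), corpus$documents)
  vectors <- build_vectors(kept)
  dist <- .soergel_cache(vectors)
  adj <- vapply(seq_len(L - 1L), function(i) {
    dist(bridge_ids[i], bridge_ids[i + 1L])
  }, numeric(1))
  others <- c()
  if (L > 2L) {
    for (i in seq_len(L - 2L)) {
      for (j in (i + 2L):L) others <- c(others, dist(bridge_ids[i],
                                                     bridge_ids[j]))
    }
  }
  kept_cluster <- setdiff(names(kept$documents), c(bridge_ids, evidence_ids))
  for (b in bridge_ids) {
    others <- c(others, vapply(kept_cluster, function(cd) dist(b, cd),
                               numeric(1)))
  }
  theta_star <- NA_real_
  if (params$chain_overlap > 0) {
    if (max(adj) >= min(others) - 0.02) {
      stop("degenerate generation: adjacent bridge distances (max ",
           round(max(adj), 3), ") do not separate from other pairs (min ",
           round(min(others), 3), "); adjust parameters")
    }
    theta_star <- (max(adj) + min(others)) / 2
  }

  sentence_labels <- do.call(rbind, lapply(corpus$documents, function(d) {
    ns <- length(d$sentences)
    data.frame(doc_id = d$doc_id, position = seq_len(ns) - 1L,
               label = ifelse(seq_len(ns) <= n_ctx, "context", "result"),
               stringsAsFactors = FALSE)
  }))
  rownames(sentence_labels) <- NULL

  entity_path <- data.frame(
    doc_id = bridge_ids,
    position = 0L,
    entity = c(bridge_ents[1L],
               if (L > 2L) bridge_ents[seq_len(L - 2L) + 1L],
               bridge_ents[L - 1L])[seq_len(L)],
    stringsAsFactors = FALSE
  )

  list(
    corpus = corpus,
    ground_truth = list(
      junctions = bridge_ids,
      theta_star = theta_star,
      adjacent_distances = adj,
      seed_keywords = list(start = kw_start, end = kw_end),
      start_id = bridge_ids[1L], end_id = bridge_ids[L],
      entity_path = entity_path,
      review_ids = review_ids,
      sentence_labels = sentence_labels
    ),
    gazetteer = gaz,
    params = params
  )
}

#' Generate labeled training sentences for the classifier
#'
#' Emulates a hand-tagged training set: abstracts whose early sentences are
#' context sentences and late sentences result sentences (so the DFT
#' distribution is skewed low for the context class), with indicator phrases
#' used predominantly (probability 0.9) by their own class and rarely
#' (probability 0.05) by the other.
#'
#' @param params a `synthesis_params` (uses `sentences_per_doc`,
#'   `context_fraction` and `rng_seed`).
#' @param n_docs number of training abstracts (default 100).
#' @return data.frame with columns `doc_id`, `position`, `text`, `label`.
#' @export
generate_labeled_sentences <- function(params = synthesis_params(),
                                       n_docs = 100L) {
  stopifnot(inherits(params, "synthesis_params"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(params$rng_seed + 1L)
  ns <- params$sentences_per_doc
  rows <- list()
  for (d in seq_len(n_docs)) {
    # the context/result boundary wobbles by one sentence around the
    # requested fraction, so a band of ambiguous positions exists but the
    # DFT feature stays strongly informative
    nc <- round(params$context_fraction * ns) +
      sample(c(-1L, 0L, 1L), 1L, prob = c(0.2, 0.6, 0.2))
    nc <- max(min(nc, ns - 1L), 1L)
    if (params$context_fraction >= 1) nc <- ns
    for (i in seq_len(ns)) {
      is_ctx <- i <= nc
      own <- if (is_ctx) .ctx_phrases else .res_phrases
      other <- if (is_ctx) .res_phrases else .ctx_phrases
      bits <- c("the topic", sprintf("item%03d", sample.int(500L, 2L)))
      if (stats::runif(1) < 0.9) bits <- c(sample(own, 1L), bits)
      if (stats::runif(1) < 0.05) bits <- c(bits, sample(other, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = sprintf("T%03d", d), position = i - 1L,
        text = paste0("We ", paste(bits, collapse = " "), "."),
        label = if (is_ctx) "context" else "result",
        dft = (i - 1L) / ns,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all synthetic artifacts to a directory
#'
#' Writes the corpus JSONL, gazetteer (one entity per line), labeled
#' training sentences TSV and the ground truth JSON.
#'
#' @param sim result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(sim$corpus, file.path(dir, "corpus.jsonl"))
  writeLines(sim$gazetteer, file.path(dir, "gazetteer.txt"))
  write_labeled_sentences(generate_labeled_sentences(sim$params),
                          file.path(dir, "training_sentences.tsv"))
  gt <- sim$ground_truth
  gt$sentence_labels <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
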