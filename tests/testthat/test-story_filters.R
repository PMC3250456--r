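test_that("classifier training reproduces priors and smoothed likelihoods", {
  set.seed(21)
  n_ctx <- 449L; n_res <- 565L
  train <- data.frame(
    doc_id = "d", position = 0L,
    text = c(rep("We investigated the topic.", n_ctx),
             rep("We observed a change.", n_res)),
    label = c(rep("context", n_ctx), rep("result", n_res)),
    dft = c(runif(n_ctx, 0, 0.5), runif(n_res, 0.5, 1)),
    stringsAsFactors = FALSE)
  model <- train_classifier(train, phrase_lexicon = c("investigated",
                                                      "observed",
                                                      "neverseen"))
  expect_equal(unname(model$prior["context"]), 449 / 1014)
  expect_equal(sum(model$prior), 1)
  # absent phrase: alpha / 2 alpha = 0.5 for both classes
  expect_equal(unname(model$phrase_likelihood["neverseen", ]),
               c(0.5, 0.5), ignore_attr = TRUE)
  # a pure-context phrase approaches likelihood 1 as alpha -> 0
  model0 <- train_classifier(train, phrase_lexicon = "investigated",
                             alpha = 1e-9)
  expect_equal(unname(model0$phrase_likelihood["investigated", "context"]), 1,
               tolerance = 1e-6)
  # a bin containing only context sentences does the same
  low_bins <- which(train$dft < 0.1)
  expect_true(all(train$label[low_bins] == "context"))
  expect_equal(unname(model0$bin_likelihood[1, "context"]), 1,
               tolerance = 1e-6)
  expect_error(train_classifier(train[train$label == "context", ]),
               "both context and result")
})

test_that("classification follows position and phrase evidence; ties go to context", {
  model <- train_classifier(generate_labeled_sentences(synthesis_params()))
  sents <- data.frame(
    doc_id = "d", position = c(0L, 5L),
    text = c("We investigated the pathway in this study.",
             "We observed a significant change in the pathway."),
    dft = c(0, 0.9), stringsAsFactors = FALSE)
  expect_equal(classify_sentences(model, sents), c("context", "result"))
  # perfectly symmetric model: equal posteriors resolve to context
  flat <- structure(list(
    prior = c(context = 0.5, result = 0.5),
    bin_likelihood = matrix(0.5, 10, 2,
                            dimnames = list(NULL, c("context", "result"))),
    phrase_likelihood = matrix(0.5, 0, 2,
                               dimnames = list(NULL, c("context", "result"))),
    phrase_lexicon = character(0), alpha = 1), class = "sentence_nb")
  expect_equal(classify_sentences(flat, sents), c("context", "context"))
})

test_that("context overlap scores token-set Jaccard over context sentences", {
  model <- train_classifier(generate_labeled_sentences(synthesis_params()))
  mk <- function(id, ctx_terms, res_terms) {
    story_document(id, title = "On things",
                   sentences = c(
                     paste0("We investigated in this study ",
                            paste(ctx_terms, collapse = " "), "."),
                     paste0("We observed a significant change in ",
                            paste(res_terms, collapse = " "), ".")),
                   mesh_terms = ctx_terms[1])
  }
  corpus <- structure(list(documents = list(
    d1 = mk("d1", c("tokena", "tokenb", "tokenc"), "tokz"),
    d2 = mk("d2", c("tokenb", "tokenc", "tokend"), "toky"),
    d3 = mk("d3", c("tokenb", "tokenc", "tokend"), "tokx")
  ), provenance = list()), class = "story_corpus")
  stop2 <- c(default_stopwords(), "we", "investigated", "study", "observed",
             "significant", "change")
  res <- context_overlap_filter(c("d1", "d2", "d3"), corpus, model,
                                j_min = 0.4, stopwords = stop2)
  # {tokena,tokenb,tokenc} vs {tokenb,tokenc,tokend} -> 2/4; identical -> 1
  expect_equal(res$link_scores, c(0.5, 1))
  expect_true(res$pass)
  expect_false(context_overlap_filter(c("d1", "d2"), corpus, model,
                                      j_min = 0.6,
                                      stopwords = stop2)$pass)
  # raising j_min never adds survivors
  for (j in c(0.1, 0.3, 0.5, 0.7)) {
    lo <- context_overlap_filter(c("d1", "d2"), corpus, model, j_min = j,
                                 stopwords = stop2)$pass
    hi <- context_overlap_filter(c("d1", "d2"), corpus, model,
                                 j_min = j + 0.2, stopwords = stop2)$pass
    expect_true(lo >= hi)
  }
})

test_that("a document with no context sentences zeroes its links", {
  model <- train_classifier(generate_labeled_sentences(synthesis_params()))
  all_result <- story_document(
    "r1", title = "On things",
    sentences = c("We observed a significant change in tokq.",
                  "We observed that it was evident in tokr."))
  ctx_doc <- story_document(
    "c1", title = "On things",
    sentences = c("We investigated in this study tokq.",
                  "We observed tokz."))
  corpus <- structure(list(documents = list(r1 = all_result, c1 = ctx_doc),
                           provenance = list()), class = "story_corpus")
  res <- context_overlap_filter(c("r1", "c1"), corpus, model, j_min = 0.05)
  expect_true(all(res$labels$r1 == "result"))
  expect_equal(res$link_scores, 0)
  expect_false(res$pass)
})

test_that("gazetteer annotation is longest-match and case-insensitive", {
  doc <- story_document("d1", title = "PARP at work",
                        sentences = c("PARP inhibits NF-kappaB.",
                                      "Nothing relevant here.",
                                      "Pyruvate kinase beats kinase alone."))
  ann <- annotate_entities(list(doc),
                           gazetteer = c("PARP", "NF-kappaB",
                                         "pyruvate kinase", "kinase"))
  expect_equal(ann$d1[[2]], sort(c("NF-kappaB", "PARP")))
  expect_equal(ann$d1[[3]], character(0))
  # overlapping candidates: the longest match wins
  expect_equal(ann$d1[[4]], c("kinase", "pyruvate kinase"))
  expect_error(annotate_entities(list(doc), gazetteer = character(0)),
               "gazetteer")
})

test_that("overlap suppression keeps only the covering entity", {
  doc <- story_document("d1", title = "x",
                        sentences = "Pyruvate kinase was measured.")
  ann <- annotate_entities(list(doc), gazetteer = c("pyruvate kinase",
                                                    "kinase"))
  expect_equal(ann$d1[[2]], "pyruvate kinase")
})

test_that("cohesion filter finds and scores entity-linked sentence paths", {
  mk <- function(id, sents) story_document(id, title = "t", sentences = sents)
  docs <- list(
    a = mk("a", "NPA binds the receptor."),
    b = mk("b", "NPA and NPB interact."),
    c = mk("c", "NPB acts downstream.")
  )
  ann <- annotate_entities(docs, gazetteer = c("NPA", "NPB"))
  res <- cohesion_filter(c("a", "b"), ann)
  expect_true(res$pass)
  expect_equal(res$score, 0.5)  # {NPA} vs {NPA, NPB}
  expect_equal(res$path$position, c(0L, 0L))
  res3 <- cohesion_filter(c("a", "b", "c"), ann)
  expect_true(res3$pass)
  # no shared entity between consecutive documents -> fail
  docs2 <- list(a = mk("a", "NPA binds."), z = mk("z", "NPC acts."))
  ann2 <- annotate_entities(docs2, gazetteer = c("NPA", "NPC"))
  expect_false(cohesion_filter(c("a", "z"), ann2)$pass)
  # removing gazetteer entries never adds survivors
  ann3 <- annotate_entities(docs, gazetteer = "NPA")
  expect_false(cohesion_filter(c("a", "b", "c"), ann3)$pass)
})

test_that("tied cohesion paths resolve to the earliest sentence positions", {
  mk <- function(id, sents) story_document(id, title = "t", sentences = sents)
  docs <- list(
    a = mk("a", c("NPA starts here.", "NPA again later.")),
    b = mk("b", c("NPA continues.", "NPA also continues."))
  )
  ann <- annotate_entities(docs, gazetteer = "NPA")
  res <- cohesion_filter(c("a", "b"), ann)
  expect_true(res$pass)
  expect_equal(res$path$position, c(0L, 0L))
})
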