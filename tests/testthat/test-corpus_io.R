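test_that("JSONL ingestion keeps well-formed records and counts drops", {
  recs <- list(
    jsonl_record("d1"), jsonl_record("d2"), jsonl_record("d3"),
    jsonl_record("d4", abstract = ""),        # no abstract -> dropped
    jsonl_record("d5", mesh_terms = character(0))  # no MeSH -> dropped
  )
  path <- write_jsonl_fixture(recs)
  corpus <- read_corpus(path, "jsonl")
  expect_s3_class(corpus, "story_corpus")
  expect_equal(length(corpus), 3L)
  expect_setequal(names(corpus$documents), c("d1", "d2", "d3"))
  expect_equal(corpus$provenance$dropped$missing_fields, 2L)
  # lossless modulo documented drops
  expect_equal(corpus$provenance$n_input,
               length(corpus) + sum(unlist(corpus$provenance$dropped)))
  # sentences were segmented
  expect_equal(length(corpus$documents$d1$sentences), 2L)
})

test_that("malformed input raises a format error naming the record", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(jsonlite::toJSON(jsonl_record("d1"), auto_unbox = TRUE),
               "{not valid json"), path)
  expect_error(read_corpus(path, "jsonl"), "line 2")
  xml_path <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><broken", xml_path)
  expect_error(read_corpus(xml_path, "medline-xml"), "malformed")
})

test_that("MEDLINE XML maps PMID, title, abstract, MeSH and types", {
  xml <- '<?xml version="1.0"?>
  <PubmedArticleSet><PubmedArticle><MedlineCitation>
    <PMID>12345</PMID>
    <Article>
      <ArticleTitle>Glutamine metabolism in tumors.</ArticleTitle>
      <Abstract><AbstractText>Cells need glutamine. It fuels growth.</AbstractText></Abstract>
      <PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>
    </Article>
    <MeshHeadingList><MeshHeading><DescriptorName>Glutamine</DescriptorName></MeshHeading></MeshHeadingList>
  </MedlineCitation></PubmedArticle></PubmedArticleSet>'
  path <- tempfile(fileext = ".xml")
  writeLines(xml, path)
  corpus <- read_corpus(path, "medline-xml")
  expect_equal(length(corpus), 1L)
  doc <- corpus$documents[["12345"]]
  expect_equal(doc$title, "Glutamine metabolism in tumors.")
  expect_equal(length(doc$sentences), 2L)
  expect_equal(doc$mesh_terms, "Glutamine")
  expect_equal(doc$publication_types, "Journal Article")
})

test_that("review filter traps tagged, titled and self-described reviews", {
  base <- function(...) story_document("x", ..., mesh_terms = "M")
  expect_true(review_filter(base(
    title = "Some topic", sentences = "A sentence.",
    publication_types = "Review")))
  expect_true(review_filter(base(
    title = "A review of the field", sentences = "A sentence.")))
  expect_true(review_filter(base(
    title = "Poly(ADP-ribose): historical perspective",
    sentences = c("Background.", "In this review we revisit the topic."))))
  # token-level title match and legitimate "is reviewed" usage
  expect_false(review_filter(base(
    title = "Genes reviewed carefully", sentences = "A sentence.")))
  expect_false(review_filter(base(
    title = "Some topic", sentences = "The mechanism is reviewed briefly.")))
  # pure predicate
  doc <- base(title = "Some topic", sentences = "A sentence.")
  expect_identical(review_filter(doc), review_filter(doc))
})

test_that("seed labeling caps per label, ranks by hits and assigns one label", {
  recs <- list(
    jsonl_record("d1", abstract = "alphakw once here. Filler text goes on."),
    jsonl_record("d2", abstract = "alphakw twice alphakw here. More filler."),
    jsonl_record("d3", abstract = "alphakw and betakw together. Filler."),
    jsonl_record("d4", abstract = "betakw alone here. Filler stays."),
    jsonl_record("d5", abstract = "Nothing relevant at all. Filler.")
  )
  corpus <- read_corpus(write_jsonl_fixture(recs), "jsonl")
  labeled <- label_seeds(corpus, list(A = "alphakw", B = "betakw"), cap = 2L)
  labs <- vapply(labeled$documents, function(d) d$seed_label %||% NA_character_,
                 character(1))
  # cap 2 on three A matches: top-ranked by hit count (d2 = 2 hits), then
  # corpus order (d1 before d3)
  expect_equal(unname(labs[c("d1", "d2")]), c("A", "A"))
  # d3 matched A and B but A was already full; it still belongs to A only
  # by first-match label order, so it stays unlabeled rather than moving to B
  expect_true(is.na(labs[["d3"]]) || labs[["d3"]] == "A")
  expect_equal(unname(labs[["d4"]]), "B")
  expect_true(is.na(labs[["d5"]]))
  # at most one label each is structural: seed_label is a scalar
  expect_error(label_seeds(corpus, list(A = character(0))), "empty keyword")
})

test_that("documents matching several labels get the first label only", {
  recs <- list(jsonl_record("d1", abstract = "alphakw and betakw. Filler."))
  corpus <- read_corpus(write_jsonl_fixture(recs), "jsonl")
  labeled <- label_seeds(corpus, list(A = "alphakw", B = "betakw"), cap = 5L)
  expect_equal(labeled$documents$d1$seed_label, "A")
})

test_that("seed pairs require term-disjoint modeled vectors", {
  corpus <- corpus_from_terms(list(s1 = c("wqa", "wqb"), s2 = c("wqa", "wqx"),
                                   e1 = c("wqc", "wqd"), e2 = c("wqb", "wqc")))
  corpus$documents$s1$seed_label <- "S"
  corpus$documents$s2$seed_label <- "S"
  corpus$documents$e1$seed_label <- "E"
  corpus$documents$e2$seed_label <- "E"
  vecs <- as_vectors(list(s1 = c(wqa = 1, wqb = 1), s2 = c(wqa = 1, wqx = 1),
                          e1 = c(wqc = 1, wqd = 1), e2 = c(wqb = 1, wqc = 1)))
  pairs <- make_seed_pairs(corpus, "S", "E", vecs)
  # s1-e2 shares wqb and must be excluded; the other three combinations are
  # disjoint
  expect_equal(nrow(pairs), 3L)
  expect_false(any(pairs$start_id == "s1" & pairs$end_id == "e2"))
  for (r in seq_len(nrow(pairs))) {
    expect_length(intersect(names(vecs$vectors[[pairs$start_id[r]]]),
                            names(vecs$vectors[[pairs$end_id[r]]])), 0L)
  }
  # empty start set
  corpus2 <- corpus
  for (id in c("s1", "s2")) corpus2$documents[[id]]$seed_label <- NULL
  expect_warning(p0 <- make_seed_pairs(corpus2, "S", "E", vecs), "no labeled")
  expect_equal(nrow(p0), 0L)
})

test_that("corpus JSONL round-trips through write and read", {
  sim <- generate_corpus(synthesis_params(docs_per_cluster = 4L))
  path <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(sim$corpus, path)
  back <- read_corpus(path, "jsonl", drop_reviews = FALSE)
  expect_setequal(names(back$documents), names(sim$corpus$documents))
  d <- sim$ground_truth$junctions[1]
  expect_equal(back$documents[[d]]$sentences, sim$corpus$documents[[d]]$sentences)
  expect_equal(back$documents[[d]]$mesh_terms, sim$corpus$documents[[d]]$mesh_terms)
})
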