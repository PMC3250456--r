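#' Construct a document
#'
#' A document is the unit the storytelling pipeline works over: an abstract
#' with its title, sentence-segmented body, controlled-vocabulary (MeSH-like)
#' terms and publication types. A document may carry at most one seed label.
#'
#' @param doc_id unique identifier (coerced to character).
#' @param title title text.
#' @param sentences character vector of abstract sentences, in order.
#' @param mesh_terms character vector of controlled-vocabulary terms.
#' @param publication_types character vector of publication type strings.
#' @param seed_label optional single seed keyword tag.
#' @return an object of class `story_document`.
#' @export
story_document <- function(doc_id, title, sentences, mesh_terms = character(0),
                           publication_types = character(0), seed_label = NULL) {
  if (length(doc_id) != 1L || !nzchar(as.character(doc_id))) {
    stop("doc_id must be a single non-empty identifier")
  }
  if (!is.null(seed_label) && length(seed_label) > 1L) {
    stop("a document carries at most one seed label")
  }
  structure(list(
    doc_id = as.character(doc_id),
    title = as.character(title),
    sentences = as.character(sentences),
    mesh_terms = as.character(mesh_terms),
    publication_types = as.character(publication_types),
    seed_label = seed_label
  ), class = "story_document")
}

#' @export
print.story_document <- function(x, ...) {
  cat("<story_document>", x$doc_id, "\n  title:", x$title,
      "\n  sentences:", length(x$sentences),
      " mesh:", length(x$mesh_terms), "\n")
  invisible(x)
}

.new_corpus <- function(documents, provenance) {
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus: ",
                               ids[duplicated(ids)][1])
  names(documents) <- ids
  structure(list(documents = documents, provenance = provenance),
            class = "story_corpus")
}

#' @export
print.story_corpus <- function(x, ...) {
  cat("<story_corpus> ", length(x$documents), " documents (source: ",
      x$provenance$source %||% "in-memory", ")\n", sep = "")
  drops <- x$provenance$dropped
  if (!is.null(drops)) {
    cat("  dropped:", paste(names(drops), unlist(drops), sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.story_corpus <- function(x) length(x$documents)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a corpus of abstracts
#'
#' Reads documents from MEDLINE XML (PubMed export) or from a JSONL dialect
#' with one JSON object per line carrying `doc_id`, `title`, `abstract`,
#' `mesh_terms` and `publication_types`. Documents missing a title, abstract
#' or MeSH terms are dropped and counted in the corpus provenance, as are
#' review papers when `drop_reviews` is set (see [review_filter()]).
#'
#' @param path input file path.
#' @param format `"jsonl"` or `"medline-xml"`.
#' @param drop_reviews apply the review filter during ingestion (default TRUE).
#' @return a `story_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "medline-xml"),
                        drop_reviews = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  records <- switch(format,
    "jsonl" = .read_jsonl_records(path),
    "medline-xml" = .read_medline_records(path)
  )
  documents <- list()
  n_missing <- 0L
  n_review <- 0L
  for (rec in records) {
    ok <- nzchar(rec$title %||% "") && nzchar(rec$abstract %||% "") &&
      length(rec$mesh_terms) > 0L
    if (!ok) { n_missing <- n_missing + 1L; next }
    doc <- story_document(rec$doc_id, rec$title,
                          split_sentences(rec$abstract),
                          rec$mesh_terms, rec$publication_types)
    if (length(doc$sentences) == 0L) { n_missing <- n_missing + 1L; next }
    if (drop_reviews && review_filter(doc)) { n_review <- n_review + 1L; next }
    documents[[length(documents) + 1L]] <- doc
  }
  .new_corpus(documents, provenance = list(
    source = paste0(format, ":", path),
    n_input = length(records),
    dropped = list(missing_fields = n_missing, review = n_review)
  ))
}

.read_jsonl_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSONL record at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$doc_id)) {
      stop("malformed JSONL record at line ", i, ": missing doc_id",
           call. = FALSE)
    }
    list(doc_id = as.character(rec$doc_id),
         title = as.character(rec$title %||% ""),
         abstract = as.character(rec$abstract %||% ""),
         mesh_terms = as.character(rec$mesh_terms %||% character(0)),
         publication_types = as.character(rec$publication_types %||% character(0)))
  })
}

.read_medline_records <- function(path) {
  xml <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed MEDLINE XML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  arts <- xml2::xml_find_all(xml, ".//MedlineCitation")
  lapply(seq_along(arts), function(i) {
    art <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, "./PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      stop("malformed MEDLINE record at position ", i, ": missing PMID",
           call. = FALSE)
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    abst <- paste(xml2::xml_text(
      xml2::xml_find_all(art, ".//Abstract/AbstractText")), collapse = " ")
    mesh <- xml2::xml_text(
      xml2::xml_find_all(art, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    ptypes <- xml2::xml_text(
      xml2::xml_find_all(art, ".//PublicationTypeList/PublicationType"))
    list(doc_id = pmid,
         title = if (is.na(title)) "" else title,
         abstract = abst, mesh_terms = mesh, publication_types = ptypes)
  })
}

#' Review-paper filter
#'
#' Flags a document for exclusion when its publication types include a review
#' type, its title contains the token "review" (token-level, so "reviewed"
#' does not match), or any abstract sentence contains the phrase "this
#' review". Case-insensitive throughout. Review papers act as "lowest common
#' denominator" hubs that short-circuit stories through topic dilution, so
#' they are pruned before any search.
#'
#' @param doc a `story_document`.
#' @return TRUE if the document should be excluded.
#' @export
review_filter <- function(doc) {
  ptypes <- tolower(doc$publication_types)
  if (any(grepl("review", ptypes, fixed = TRUE))) return(TRUE)
  if (grepl("\\breview\\b", tolower(doc$title), perl = TRUE)) return(TRUE)
  any(grepl("this review", tolower(doc$sentences), fixed = TRUE))
}

#' Label seed documents by keyword
#'
#' Assigns to each document at most one label: the first label (in the order
#' of `keyword_sets`) for which any keyword occurs case-insensitively in the
#' title or abstract. Per label, at most `cap` documents are kept, ranked by
#' total keyword occurrence count with ties broken by corpus order.
#'
#' @param corpus a `story_corpus`.
#' @param keyword_sets named list, label -> character vector of keywords.
#' @param cap maximum labeled documents per label (default 700).
#' @return the corpus with `seed_label` set on the selected documents.
#' @export
label_seeds <- function(corpus, keyword_sets, cap = 700L) {
  stopifnot(inherits(corpus, "story_corpus"))
  if (length(keyword_sets) == 0L || is.null(names(keyword_sets)) ||
      any(!nzchar(names(keyword_sets)))) {
    stop("keyword_sets must be a named list of keyword vectors")
  }
  if (any(vapply(keyword_sets, length, integer(1)) == 0L)) {
    stop("empty keyword set for label: ",
         names(keyword_sets)[vapply(keyword_sets, length, integer(1)) == 0L][1])
  }
  if (cap < 1L) stop("cap must be >= 1")

  texts <- vapply(corpus$documents, function(d) tolower(.doc_text(d)),
                  character(1))
  labels <- names(keyword_sets)
  assigned <- rep(NA_character_, length(texts))
  # a document belongs to the first label (in keyword_sets order) any of
  # whose keywords it matches; it never falls through to a later label,
  # even when that first label's cap is already full
  claimed <- logical(length(texts))
  for (lab in labels) {
    kw <- tolower(keyword_sets[[lab]])
    hits <- vapply(kw, function(k) {
      vapply(texts, function(tx) {
        m <- gregexpr(k, tx, fixed = TRUE)[[1]]
        if (m[1] == -1L) 0L else length(m)
      }, integer(1))
    }, integer(length(texts)))
    counts <- rowSums(matrix(hits, nrow = length(texts)))
    sel <- which(!claimed & counts > 0L)
    claimed[sel] <- TRUE
    if (length(sel) > 0L) {
      ord <- sel[order(-counts[sel], sel)]
      keep <- ord[seq_len(min(cap, length(ord)))]
      assigned[keep] <- lab
    }
  }
  for (i in which(!is.na(assigned))) {
    corpus$documents[[i]]$seed_label <- assigned[i]
  }
  corpus$provenance$seed_labels <- table(assigned[!is.na(assigned)])
  corpus
}

#' Construct term-disjoint start-end pairs
#'
#' Forms every (start, end) combination of seed-labeled documents whose
#' modeled term sets are disjoint, guaranteeing that discovered stories are
#' not trivial overlaps. Ordering is deterministic (start id, then end id).
#'
#' @param corpus a labeled `story_corpus`.
#' @param start_labels labels marking start documents.
#' @param end_labels labels marking end documents.
#' @param vectors a `story_vectors` object from [build_vectors()].
#' @return data.frame with columns `start_id`, `end_id`.
#' @export
make_seed_pairs <- function(corpus, start_labels, end_labels, vectors) {
  stopifnot(inherits(corpus, "story_corpus"), inherits(vectors, "story_vectors"))
  labs <- vapply(corpus$documents, function(d) d$seed_label %||% NA_character_,
                 character(1))
  starts <- names(corpus$documents)[labs %in% start_labels]
  ends <- names(corpus$documents)[labs %in% end_labels]
  if (length(starts) == 0L || length(ends) == 0L) {
    warning("no labeled start or end documents; returning empty pair list")
    return(data.frame(start_id = character(0), end_id = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- sort(starts)
  ends <- sort(ends)
  out <- list()
  for (s in starts) {
    st <- names(vectors$vectors[[s]])
    for (e in ends) {
      if (s == e) next
      if (length(intersect(st, names(vectors$vectors[[e]]))) == 0L) {
        out[[length(out) + 1L]] <- c(s, e)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_id = character(0), end_id = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(start_id = m[, 1], end_id = m[, 2], stringsAsFactors = FALSE)
}

#' Write a corpus as JSONL
#'
#' One JSON object per line with the five document fields; the inverse of
#' `read_corpus(format = "jsonl")` up to sentence re-segmentation.
#'
#' @param corpus a `story_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "story_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    jsonlite::toJSON(list(
      doc_id = d$doc_id, title = d$title,
      abstract = paste(d$sentences, collapse = " "),
      mesh_terms = d$mesh_terms,
      publication_types = d$publication_types
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
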