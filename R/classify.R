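# context/result sentence classification: naive Bayes over DFT bins and
# indicator phrases

# bin index 1..10 for a DFT value in [0, 1]; edges [0,.1), ..., [.9,1]
.dft_bin <- function(dft) pmin(floor(dft * 10), 9) + 1L

# ensure the sentence table carries a dft column (position / sentences-in-doc)
.with_dft <- function(sentences) {
  if (!"dft" %in% names(sentences)) {
    ns <- stats::ave(sentences$position, sentences$doc_id, FUN = length)
    sentences$dft <- sentences$position / ns
  }
  sentences
}

.phrase_present <- function(texts, phrase) {
  grepl(phrase, tolower(texts), fixed = TRUE)
}

#' Train the context/result sentence classifier
#'
#' Most abstracts first state background and methodology ("context") and then
#' findings ("result"), so a sentence's relative position, its Distance From
#' Title (DFT = preceding sentences / total sentences), is informative about
#' its role, as is the presence of indicator phrases ("investigated",
#' "observed", ...). This fits a naive Bayes model with class priors, one
#' feature per DFT decile bin, and one presence feature per indicator phrase.
#' Per-bin and per-phrase class probabilities are tallied among the sentences
#' in that bin (or containing that phrase) with Laplace smoothing `alpha`.
#'
#' @param sentences data.frame with columns `doc_id`, `position` (0-based),
#'   `text`, `label` (values "context"/"result"); an optional `dft` column
#'   overrides the position-derived value.
#' @param phrase_lexicon character vector of indicator phrases.
#' @param alpha Laplace smoothing constant (default 1).
#' @return a `sentence_nb` model.
#' @export
train_classifier <- function(sentences, phrase_lexicon = default_phrase_lexicon(),
                             alpha = 1) {
  stopifnot(is.data.frame(sentences))
  need <- c("doc_id", "position", "text", "label")
  if (!all(need %in% names(sentences))) {
    stop("sentences must have columns ", paste(need, collapse = ", "))
  }
  classes <- c("context", "result")
  if (!all(classes %in% sentences$label)) {
    stop("training data must contain both context and result sentences")
  }
  sentences <- .with_dft(sentences)
  n <- nrow(sentences)
  prior <- c(context = sum(sentences$label == "context") / n,
             result = sum(sentences$label == "result") / n)
  bins <- .dft_bin(sentences$dft)
  bin_likelihood <- matrix(NA_real_, nrow = 10L, ncol = 2L,
                           dimnames = list(NULL, classes))
  for (i in 1:10) {
    in_bin <- bins == i
    tot <- sum(in_bin)
    for (cl in classes) {
      bin_likelihood[i, cl] <-
        (sum(in_bin & sentences$label == cl) + alpha) / (tot + 2 * alpha)
    }
  }
  phrase_likelihood <- matrix(NA_real_, nrow = length(phrase_lexicon),
                              ncol = 2L,
                              dimnames = list(phrase_lexicon, classes))
  for (ph in phrase_lexicon) {
    has <- .phrase_present(sentences$text, ph)
    tot <- sum(has)
    for (cl in classes) {
      phrase_likelihood[ph, cl] <-
        (sum(has & sentences$label == cl) + alpha) / (tot + 2 * alpha)
    }
  }
  structure(list(prior = prior, bin_likelihood = bin_likelihood,
                 phrase_likelihood = phrase_likelihood,
                 phrase_lexicon = phrase_lexicon, alpha = alpha),
            class = "sentence_nb")
}

#' @export
print.sentence_nb <- function(x, ...) {
  cat("<sentence_nb> priors: context =", round(x$prior["context"], 3),
      ", result =", round(x$prior["result"], 3), ";",
      length(x$phrase_lexicon), "indicator phrases\n")
  invisible(x)
}

#' Classify sentences as context or result
#'
#' Scores each class as prior times DFT-bin likelihood times the likelihoods
#' of the indicator phrases present in the sentence (presence-only features:
#' an absent phrase contributes no factor), and returns the argmax. Exact
#' ties go to "context".
#'
#' @param model a `sentence_nb` model.
#' @param sentences data.frame with columns `doc_id`, `position`, `text`
#'   (and optionally `dft`).
#' @return character vector of labels, one per row.
#' @export
classify_sentences <- function(model, sentences) {
  stopifnot(inherits(model, "sentence_nb"), is.data.frame(sentences))
  sentences <- .with_dft(sentences)
  bins <- .dft_bin(sentences$dft)
  lower <- tolower(sentences$text)
  out <- character(nrow(sentences))
  for (r in seq_len(nrow(sentences))) {
    sc <- log(model$prior) + log(model$bin_likelihood[bins[r], ])
    for (ph in model$phrase_lexicon) {
      if (grepl(ph, lower[r], fixed = TRUE)) {
        sc <- sc + log(model$phrase_likelihood[ph, ])
      }
    }
    out[r] <- if (sc["result"] > sc["context"] + 1e-12) "result" else "context"
  }
  out
}

# corpus documents -> sentence table for classification
.sentence_table <- function(docs) {
  rows <- lapply(docs, function(d) {
    ns <- length(d$sentences)
    if (ns == 0L) return(NULL)
    data.frame(doc_id = d$doc_id, position = seq_len(ns) - 1L,
               text = d$sentences, dft = (seq_len(ns) - 1L) / ns,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Read or write sentence training data as TSV
#'
#' Plain TSV with columns doc_id, position, text, label.
#'
#' @param path file path.
#' @return data.frame of labeled sentences.
#' @export
read_labeled_sentences <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' @rdname read_labeled_sentences
#' @param sentences labeled sentence data.frame.
#' @export
write_labeled_sentences <- function(sentences, path) {
  utils::write.table(sentences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
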