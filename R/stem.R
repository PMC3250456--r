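#' Porter stemmer
#'
#' Reduces English words to their stems using the Porter (1980) suffix-stripping
#' algorithm (the original rule set, not the later "Porter2" revision). Words
#' shorter than three letters, and character sequences containing non-letters,
#' are returned unchanged.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("studies", "relational", "oscillators"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  uw <- unique(words)
  stems <- vapply(uw, porter_stem1, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

# consonant map: TRUE where the letter acts as a consonant.
# y is a consonant unless preceded by a consonant (then it acts as a vowel);
# a leading y is a consonant.
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# measure m of a stem: number of VC blocks in [C](VC)^m[V]
.porter_m <- function(w) {
  if (!nzchar(w)) return(0L)
  cons <- .porter_cons(strsplit(w, "", fixed = TRUE)[[1]])
  r <- rle(cons)$values
  sum(!r[-length(r)] & r[-1L])
}

.porter_has_vowel <- function(w) {
  if (!nzchar(w)) return(FALSE)
  any(!.porter_cons(strsplit(w, "", fixed = TRUE)[[1]]))
}

.porter_ends_dblc <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  a == b && .porter_cons(strsplit(w, "", fixed = TRUE)[[1]])[n]
}

# *o: stem ends cvc where the final consonant is not w, x or y
.porter_ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- .porter_cons(strsplit(w, "", fixed = TRUE)[[1]])
  last <- substr(w, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.chop <- function(w, s) substr(w, 1L, nchar(w) - nchar(s))

# apply the longest matching suffix rule whose measure condition holds;
# rules is list(c(suffix, replacement)), min_m the measure threshold on the stem
.porter_rule_step <- function(w, rules, min_m) {
  sufs <- vapply(rules, `[[`, character(1), 1L)
  hit <- which(vapply(sufs, function(s) endsWith(w, s), logical(1)))
  if (length(hit) == 0L) return(w)
  j <- hit[which.max(nchar(sufs[hit]))]
  stem <- .chop(w, sufs[j])
  if (.porter_m(stem) > min_m) paste0(stem, rules[[j]][2L]) else w
}

porter_stem1 <- function(w) {
  if (nchar(w) < 3L || grepl("[^a-z]", w)) return(w)

  # step 1a
  if (endsWith(w, "sses")) {
    w <- paste0(.chop(w, "sses"), "ss")
  } else if (endsWith(w, "ies")) {
    w <- paste0(.chop(w, "ies"), "i")
  } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
    w <- .chop(w, "s")
  }

  # step 1b
  cleanup <- FALSE
  if (endsWith(w, "eed")) {
    if (.porter_m(.chop(w, "eed")) > 0L) w <- .chop(w, "d")
  } else if (endsWith(w, "ed") && .porter_has_vowel(.chop(w, "ed"))) {
    w <- .chop(w, "ed"); cleanup <- TRUE
  } else if (endsWith(w, "ing") && .porter_has_vowel(.chop(w, "ing"))) {
    w <- .chop(w, "ing"); cleanup <- TRUE
  }
  if (cleanup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_ends_dblc(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, substr(w, nchar(w), nchar(w)))
    } else if (.porter_m(w) == 1L && .porter_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (endsWith(w, "y") && .porter_has_vowel(.chop(w, "y"))) {
    w <- paste0(.chop(w, "y"), "i")
  }

  # step 2 (m > 0)
  w <- .porter_rule_step(w, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
    c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
    c("iviti", "ive"), c("biliti", "ble")
  ), 0L)

  # step 3 (m > 0)
  w <- .porter_rule_step(w, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  ), 0L)

  # step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  sufs4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  hit <- sufs4[vapply(sufs4, function(s) endsWith(w, s), logical(1))]
  if (length(hit) > 0L) {
    s <- hit[which.max(nchar(hit))]
    stem <- .chop(w, s)
    ok <- .porter_m(stem) > 1L
    if (s == "ion") {
      ok <- ok && nzchar(stem) &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
    }
    if (ok) w <- stem
  }

  # step 5a
  if (endsWith(w, "e")) {
    stem <- .chop(w, "e")
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_ends_cvc(stem))) w <- stem
  }

  # step 5b
  if (.porter_m(w) > 1L && .porter_ends_dblc(w) && endsWith(w, "l")) {
    w <- .chop(w, "l")
  }

  w
}
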