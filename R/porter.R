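# Porter (1980) suffix-stripping algorithm, original rule set.
# Letters are classified per Porter's definition: a,e,i,o,u are vowels and
# 'y' is a vowel exactly when the preceding letter is a consonant.

.p_letters <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

.p_is_cons <- function(ltr, i) {
  ch <- ltr[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(ltr, i - 1L))
  }
  TRUE
}

.p_types <- function(ltr) {
  vapply(seq_along(ltr), function(i) .p_is_cons(ltr, i), logical(1))
}

# m of Porter's [C](VC){m}[V] form: number of vowel-run -> consonant-run
# transitions.
.p_measure <- function(w) {
  ltr <- .p_letters(w)
  if (!length(ltr)) return(0L)
  runs <- rle(.p_types(ltr))$values
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1L])
}

.p_has_vowel <- function(w) {
  ltr <- .p_letters(w)
  length(ltr) > 0L && any(!.p_types(ltr))
}

# *d: ends with a double consonant.
.p_double_cons <- function(w) {
  ltr <- .p_letters(w)
  n <- length(ltr)
  n >= 2L && ltr[n] == ltr[n - 1L] && .p_is_cons(ltr, n)
}

# *o: ends cvc where the final consonant is not w, x or y.
.p_cvc <- function(w) {
  ltr <- .p_letters(w)
  n <- length(ltr)
  if (n < 3L) return(FALSE)
  .p_is_cons(ltr, n - 2L) && !.p_is_cons(ltr, n - 1L) && .p_is_cons(ltr, n) &&
    !(ltr[n] %in% c("w", "x", "y"))
}

.p_ends <- function(w, suf) {
  nc <- nchar(w)
  ns <- nchar(suf)
  nc >= ns && substr(w, nc - ns + 1L, nc) == suf
}

.p_chop <- function(w, n) substr(w, 1L, nchar(w) - n)

# Apply the first rule whose suffix matches; a matched suffix whose condition
# fails still terminates the step (Porter's longest-match-then-test rule; the
# lists are ordered so the first match is the longest).
.p_rule_step <- function(w, rules, min_measure) {
  for (r in rules) {
    if (.p_ends(w, r[[1L]])) {
      stem <- .p_chop(w, nchar(r[[1L]]))
      if (.p_measure(stem) > min_measure) w <- paste0(stem, r[[2L]])
      return(w)
    }
  }
  w
}

.p_step2_rules <- list(
  list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
  list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
  list("alli", "al"), list("entli", "ent"), list("eli", "e"),
  list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
  list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
  list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
  list("iviti", "ive"), list("biliti", "ble")
)

.p_step3_rules <- list(
  list("icate", "ic"), list("ative", ""), list("alize", "al"),
  list("iciti", "ic"), list("ical", "ic"), list("ful", ""), list("ness", "")
)

.p_step4_sufs <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # Step 1a
  if (.p_ends(w, "sses")) {
    w <- .p_chop(w, 2L)
  } else if (.p_ends(w, "ies")) {
    w <- .p_chop(w, 2L)
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- .p_chop(w, 1L)
  }

  # Step 1b
  cleanup <- FALSE
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_chop(w, 3L)) > 0L) w <- .p_chop(w, 1L)
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_chop(w, 2L))) {
    w <- .p_chop(w, 2L)
    cleanup <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_chop(w, 3L))) {
    w <- .p_chop(w, 3L)
    cleanup <- TRUE
  }
  if (cleanup) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !.p_ends(w, "l") && !.p_ends(w, "s") && !.p_ends(w, "z")) {
      w <- .p_chop(w, 1L)
    } else if (.p_measure(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_chop(w, 1L))) {
    w <- paste0(.p_chop(w, 1L), "i")
  }

  # Steps 2 and 3 (condition m > 0)
  w <- .p_rule_step(w, .p_step2_rules, 0L)
  w <- .p_rule_step(w, .p_step3_rules, 0L)

  # Step 4 (condition m > 1; "ion" additionally requires stem ending s or t)
  for (suf in .p_step4_sufs) {
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      ok <- .p_measure(stem) > 1L
      if (suf == "ion") ok <- ok && (.p_ends(stem, "s") || .p_ends(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (.p_ends(w, "e")) {
    stem <- .p_chop(w, 1L)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }

  # Step 5b
  if (.p_measure(w) > 1L && .p_double_cons(w) && .p_ends(w, "l")) {
    w <- .p_chop(w, 1L)
  }

  w
}

#' Stem a token with the Porter algorithm
#'
#' Applies the original Porter suffix-stripping algorithm to each token after
#' lowercasing. Tokens of one or two characters are returned unchanged, as the
#' algorithm prescribes.
#'
#' @param word Character vector of single tokens (no internal whitespace).
#' @return Character vector of stems, same length as `word`.
#' @examples
#' stem_token(c("thickening", "thickened", "necrosis"))
#' @export
stem_token <- function(word) {
  stopifnot(is.character(word))
  vapply(tolower(word), .porter1, character(1), USE.NAMES = FALSE)
}
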