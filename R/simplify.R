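# Replacement of mapped terms by consumer-preferred terms: overlap
# resolution, bracket marking, article adjustment, case preservation, and an
# optional same-stem skip guard. All spans are 0-based half-open character
# offsets.

#' Replacement options
#'
#' Defaults reproduce the reference pipeline: replacements are marked with
#' literal square brackets (`[preferred term]`), articles *a*/*an* are
#' adjusted to the following word's initial letter, leading capitalization
#' is transferred, and lexically similar pairs are still replaced (the stem
#' guard is opt-in).
#'
#' @param mark_brackets Wrap every replacement in square brackets.
#' @param skip_if_same_stem Leave a term untouched when the similarity
#'   classifier labels the (term, preferred term) pair Similar.
#' @param adjust_articles Fix a/an agreement before a replacement.
#' @param preserve_case Transfer a leading capital from the original surface
#'   to the replacement; fully uppercase originals (acronyms) transfer no
#'   casing.
#' @return A list of class `chv_replacement_options`.
#' @export
replacement_options <- function(mark_brackets = TRUE,
                                skip_if_same_stem = FALSE,
                                adjust_articles = TRUE,
                                preserve_case = TRUE) {
  structure(list(mark_brackets = isTRUE(mark_brackets),
                 skip_if_same_stem = isTRUE(skip_if_same_stem),
                 adjust_articles = isTRUE(adjust_articles),
                 preserve_case = isTRUE(preserve_case)),
            class = "chv_replacement_options")
}

#' Resolve overlapping term mappings
#'
#' Selects a pairwise-disjoint subset of a document's mappings greedily by a
#' fixed priority: longer span first, then smaller start, then higher score,
#' then lexicographically smaller CUI. Deterministic and independent of the
#' input row order. The result is sorted by start.
#'
#' @param mappings A data.frame of term mappings for a single document.
#' @return The selected mappings, sorted by `start`.
#' @export
resolve_overlaps <- function(mappings) {
  if (!nrow(mappings)) return(mappings)
  if (length(unique(mappings$doc_id)) > 1L) {
    chv_error("resolve_overlaps expects mappings of a single document",
              "chv_config_error")
  }
  len <- mappings$end - mappings$start
  ord <- order(-len, mappings$start, -mappings$score, mappings$cui)
  cand <- mappings[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ks <- which(kept)
    clash <- any(cand$start[i] < cand$end[ks] & cand$end[i] > cand$start[ks])
    if (!clash) kept[i] <- TRUE
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjust an indefinite article for a replacement word
#'
#' `a` becomes `an` when the following word starts with a vowel letter and
#' `an` becomes `a` when it does not; capitalization of the article is
#' preserved and any other token is returned unchanged. The rule is
#' letter-level, not phonetic ("an hour" is out of scope).
#'
#' @param article_token The token preceding the replacement.
#' @param replacement_first_word First word of the replacement text.
#' @return The adjusted article (or the token unchanged).
#' @examples
#' adjust_article("a", "effusion")
#' adjust_article("an", "mass")
#' @export
adjust_article <- function(article_token, replacement_first_word) {
  if (!article_token %in% c("a", "an", "A", "An")) return(article_token)
  vowel <- grepl("^[aeiouAEIOU]", replacement_first_word)
  out <- if (vowel) "an" else "a"
  if (substr(article_token, 1L, 1L) == "A") {
    out <- paste0(toupper(substr(out, 1L, 1L)), substr(out, 2L, nchar(out)))
  }
  out
}

.is_all_caps <- function(s) {
  letters_only <- gsub("[^A-Za-z]", "", s)
  nchar(letters_only) > 1L && s == toupper(s)
}

.transfer_case <- function(surface, replacement) {
  first <- substr(surface, 1L, 1L)
  if (grepl("[A-Z]", first) && !.is_all_caps(surface)) {
    replacement <- paste0(toupper(substr(replacement, 1L, 1L)),
                          substr(replacement, 2L, nchar(replacement)))
  }
  replacement
}

#' Apply preferred-term replacements to a document
#'
#' Substitutes each mapped span by the preferred term of its concept,
#' wrapped in square brackets when `mark_brackets` is on. Mappings whose CUI
#' has no preferred term are recorded with action `skipped_no_pt` and listed
#' in `unmapped_spans`; with `skip_if_same_stem` on, pairs the similarity
#' classifier labels Similar are recorded as `skipped_similar` and the text
#' left intact. The replacement log is complete enough to reverse: applying
#' the recorded substitutions backwards reconstructs the original text
#' byte-for-byte (see [revert_simplification()]).
#'
#' @param text Document text.
#' @param mappings Pairwise-disjoint mappings (run [resolve_overlaps()]
#'   first); overlap raises a `chv_overlap_error`.
#' @param index A `chv_index`.
#' @param options A [replacement_options()] list.
#' @param doc_id Document identifier stored on the result.
#' @return An object of class `chv_simplified`: `doc_id`, `original_text`,
#'   `simplified_text`, `replacements` (data.frame with input/output spans,
#'   surfaces, CUI, action), `articles` (article adjustments with spans) and
#'   `unmapped_spans`.
#' @export
apply_replacements <- function(text, mappings, index,
                               options = replacement_options(),
                               doc_id = if (nrow(mappings)) mappings$doc_id[1] else "doc") {
  stopifnot(inherits(index, "chv_index"))
  if (!inherits(options, "chv_replacement_options")) {
    options <- do.call(replacement_options, as.list(options))
  }
  mappings <- mappings[order(mappings$start), , drop = FALSE]
  if (nrow(mappings)) {
    if (any(mappings$start < 0L) || any(mappings$end > nchar(text)) ||
        any(mappings$start >= mappings$end)) {
      chv_error("mapping span outside the document", "chv_span_error")
    }
    if (nrow(mappings) > 1L &&
        any(mappings$start[-1L] < mappings$end[-nrow(mappings)])) {
      chv_error("overlapping mappings; run resolve_overlaps() first",
                "chv_overlap_error")
    }
  }

  rep_rows <- list()
  art_rows <- list()
  unmapped <- list()
  pieces <- character(0)
  cursor0 <- 0L
  delta <- 0L

  for (i in seq_len(nrow(mappings))) {
    m <- mappings[i, ]
    pref <- preferred_term(index, m$cui)
    action <- "replaced"
    if (is.na(pref)) {
      action <- "skipped_no_pt"
    } else if (options$skip_if_same_stem) {
      sim <- tryCatch(classify_similarity(m$surface, pref),
                      chv_classification_error = function(e) "different")
      if (sim == "similar") action <- "skipped_similar"
    }

    gap <- substr(text, cursor0 + 1L, m$start)

    if (action == "replaced") {
      rep_cased <- if (options$preserve_case) {
        .transfer_case(m$surface, pref)
      } else {
        pref
      }
      if (options$adjust_articles) {
        am <- regexpr("(?<![A-Za-z])[Aa]n?(?=[ \t]+$)", gap, perl = TRUE)
        if (am[1L] != -1L) {
          art <- regmatches(gap, am)
          first_word <- sub("[^A-Za-z0-9].*$", "", rep_cased)
          new_art <- adjust_article(art, first_word)
          if (new_art != art) {
            art_in0 <- cursor0 + am[1L] - 1L
            art_rows[[length(art_rows) + 1L]] <- data.frame(
              in_start = art_in0, in_end = art_in0 + nchar(art),
              out_start = art_in0 + delta,
              out_end = art_in0 + delta + nchar(new_art),
              original = art, replacement = new_art,
              stringsAsFactors = FALSE)
            regmatches(gap, am) <- new_art
            delta <- delta + nchar(new_art) - nchar(art)
          }
        }
      }
      written <- if (options$mark_brackets) {
        paste0("[", rep_cased, "]")
      } else {
        rep_cased
      }
      out_start <- m$start + delta
      pieces <- c(pieces, gap, written)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        in_start = m$start, in_end = m$end,
        out_start = out_start, out_end = out_start + nchar(written),
        original = m$surface, replacement = rep_cased, cui = m$cui,
        action = action, stringsAsFactors = FALSE)
      delta <- delta + nchar(written) - (m$end - m$start)
    } else {
      pieces <- c(pieces, gap, m$surface)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        in_start = m$start, in_end = m$end,
        out_start = m$start + delta, out_end = m$end + delta,
        original = m$surface, replacement = NA_character_, cui = m$cui,
        action = action, stringsAsFactors = FALSE)
      if (action == "skipped_no_pt") {
        unmapped[[length(unmapped) + 1L]] <- data.frame(
          start = m$start, end = m$end, surface = m$surface, cui = m$cui,
          stringsAsFactors = FALSE)
      }
    }
    cursor0 <- m$end
  }
  pieces <- c(pieces, substr(text, cursor0 + 1L, nchar(text)))

  empty_rep <- data.frame(in_start = integer(0), in_end = integer(0),
                          out_start = integer(0), out_end = integer(0),
                          original = character(0), replacement = character(0),
                          cui = character(0), action = character(0),
                          stringsAsFactors = FALSE)
  empty_art <- data.frame(in_start = integer(0), in_end = integer(0),
                          out_start = integer(0), out_end = integer(0),
                          original = character(0), replacement = character(0),
                          stringsAsFactors = FALSE)
  empty_unm <- data.frame(start = integer(0), end = integer(0),
                          surface = character(0), cui = character(0),
                          stringsAsFactors = FALSE)
  structure(list(doc_id = doc_id,
                 original_text = text,
                 simplified_text = paste(pieces, collapse = ""),
                 replacements = if (length(rep_rows)) do.call(rbind, rep_rows) else empty_rep,
                 articles = if (length(art_rows)) do.call(rbind, art_rows) else empty_art,
                 unmapped_spans = if (length(unmapped)) do.call(rbind, unmapped) else empty_unm),
            class = "chv_simplified")
}

#' @export
print.chv_simplified <- function(x, ...) {
  acts <- table(factor(x$replacements$action,
                       c("replaced", "skipped_similar", "skipped_no_pt")))
  cat(sprintf("<chv_simplified> %s: %d replaced, %d skipped (similar), %d skipped (no preferred term)\n",
              x$doc_id, acts[["replaced"]], acts[["skipped_similar"]],
              acts[["skipped_no_pt"]]))
  invisible(x)
}

#' Undo recorded replacements
#'
#' Reconstructs the original document from a simplified one by applying the
#' recorded replacement and article-adjustment log in reverse.
#'
#' @param simplified A `chv_simplified` object.
#' @return The reconstructed original text.
#' @export
revert_simplification <- function(simplified) {
  stopifnot(inherits(simplified, "chv_simplified"))
  reps <- simplified$replacements
  reps <- reps[reps$action == "replaced", c("out_start", "out_end", "original")]
  arts <- simplified$articles[, c("out_start", "out_end", "original")]
  events <- rbind(reps, arts)
  text <- simplified$simplified_text
  if (nrow(events)) {
    events <- events[order(-events$out_start), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      text <- paste0(substr(text, 1L, events$out_start[i]),
                     events$original[i],
                     substr(text, events$out_end[i] + 1L, nchar(text)))
    }
  }
  text
}
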