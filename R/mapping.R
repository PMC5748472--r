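# Term-to-concept mapping: MetaMap fielded MMI ingestion and a built-in
# dictionary longest-match mapper, with score filtering and abbreviation
# pre-expansion.

#' Parse MetaMap fielded MMI output
#'
#' Reads pipe-delimited fielded MMI lines (one concept hit per line) into a
#' data frame. Field layout: document id, the literal `MMI`, evaluation score
#' (0--1000; decimal scores from some MetaMap releases are rounded to the
#' nearest integer), UMLS preferred name, CUI, bracketed semantic types,
#' trigger information, location, positional information
#' (slash-separated start/length pairs, groups separated by commas or
#' semicolons, flattened), and optional treecodes.
#'
#' At most 4 distinct trigger terms are retained per record, in order of
#' appearance, deduplicated case-insensitively.
#'
#' @param lines Character vector of lines, or a path to an MMI file.
#' @param doc_text Optional document text; if given, spans exceeding its
#'   length produce a warning here (strict checking happens in
#'   [mmi_to_mappings()]).
#' @return A data.frame with columns `doc_id`, `score` (integer), `umls_name`,
#'   `cui`, and list columns `sem_types`, `triggers`, `spans` (two-column
#'   integer matrix, start/length).
#' @details Lines whose second field is not `MMI` are skipped with a warning;
#'   an unparsable score, CUI or positional field raises a `chv_format_error`
#'   with the line number.
#' @export
parse_mmi <- function(lines, doc_text = NULL) {
  if (length(lines) == 1L && !grepl("|", lines, fixed = TRUE) &&
      file.exists(lines)) {
    lines <- readLines(lines, encoding = "UTF-8", warn = FALSE)
  }
  keep <- which(nzchar(trimws(lines)))
  empty <- data.frame(doc_id = character(0), score = integer(0),
                      umls_name = character(0), cui = character(0),
                      stringsAsFactors = FALSE)
  empty$sem_types <- list()
  empty$triggers <- list()
  empty$spans <- list()
  if (!length(keep)) return(empty)

  fields <- split_pipes(lines[keep])
  recs <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ln <- keep[i]
    if (length(f) < 2L || f[2L] != "MMI") {
      warning(sprintf("skipping non-MMI line %d", ln), call. = FALSE)
      next
    }
    if (length(f) < 9L) {
      chv_error(sprintf("line %d: MMI record has %d fields, expected >= 9",
                        ln, length(f)), "chv_format_error")
    }
    score_num <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(score_num)) {
      chv_error(sprintf("line %d: unparsable score '%s'", ln, f[3L]),
                "chv_format_error")
    }
    score <- as.integer(round(score_num))
    if (score < 0L || score > 1000L) {
      chv_error(sprintf("line %d: score %s outside 0-1000", ln, f[3L]),
                "chv_format_error")
    }
    if (!is_valid_cui(f[5L])) {
      chv_error(sprintf("line %d: malformed CUI '%s'", ln, f[5L]),
                "chv_format_error")
    }
    sem <- trimws(strsplit(gsub("^\\[|\\]$", "", trimws(f[6L])), ",")[[1]])
    sem <- sem[nzchar(sem)]

    trig_raw <- regmatches(f[7L], gregexpr('"[^"]*"', f[7L]))[[1]]
    trig <- gsub('^"|"$', "", trig_raw)
    trig <- trig[nzchar(trig)]
    trig <- trig[!duplicated(tolower(trig))]
    if (length(trig) > 4L) trig <- trig[1:4]

    pos_field <- gsub("^\\[|\\]$", "", trimws(f[9L]))
    spans <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "length")))
    if (nzchar(pos_field)) {
      groups <- strsplit(pos_field, "[;,]")[[1]]
      groups <- trimws(groups)
      groups <- groups[nzchar(groups)]
      parsed <- lapply(groups, function(g) {
        p <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
        if (length(p) != 2L || anyNA(p) || any(p < 0L)) {
          chv_error(sprintf("line %d: unparsable positional info '%s'", ln, g),
                    "chv_format_error")
        }
        p
      })
      spans <- do.call(rbind, parsed)
      colnames(spans) <- c("start", "length")
    }
    if (!is.null(doc_text) && nrow(spans) &&
        any(spans[, 1L] + spans[, 2L] > nchar(doc_text) + 1L)) {
      warning(sprintf("line %d: span extends beyond the supplied text", ln),
              call. = FALSE)
    }
    recs[[length(recs) + 1L]] <-
      list(doc_id = f[1L], score = score, umls_name = f[4L], cui = f[5L],
           sem_types = sem, triggers = trig, spans = spans)
  }
  if (!length(recs)) return(empty)
  out <- data.frame(doc_id = vapply(recs, `[[`, "", "doc_id"),
                    score = vapply(recs, `[[`, 0L, "score"),
                    umls_name = vapply(recs, `[[`, "", "umls_name"),
                    cui = vapply(recs, `[[`, "", "cui"),
                    stringsAsFactors = FALSE)
  out$sem_types <- lapply(recs, `[[`, "sem_types")
  out$triggers <- lapply(recs, `[[`, "triggers")
  out$spans <- lapply(recs, `[[`, "spans")
  out
}

#' Serialize MMI records back to fielded lines
#'
#' @param records A data.frame as returned by [parse_mmi()].
#' @return Character vector of pipe-delimited MMI lines.
#' @export
format_mmi <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    spans <- records$spans[[i]]
    pos <- paste(paste(spans[, 1L], spans[, 2L], sep = "/"), collapse = ";")
    trig <- paste0("[", paste(sprintf('"%s"-tx-1-"%s"-noun-0',
                                      records$triggers[[i]],
                                      records$triggers[[i]]),
                              collapse = ","), "]")
    sem <- paste0("[", paste(records$sem_types[[i]], collapse = ","), "]")
    paste(records$doc_id[i], "MMI", records$score[i], records$umls_name[i],
          records$cui[i], sem, trig, "TX", pos, "", sep = "|")
  }, character(1))
}

#' Filter MMI records by score and semantic type
#'
#' Keeps records whose evaluation score is at least `min_score` (default 500
#' of 1000, a deliberately low threshold that casts a wide net) and, when
#' `allowed_sem_types` is given, whose semantic types intersect it. By
#' default no semantic-type restriction is applied, i.e. all semantic types
#' are included. Order is preserved; the operation is idempotent.
#'
#' @param records A data.frame from [parse_mmi()].
#' @param min_score Integer threshold in 0--1000; a record scoring exactly
#'   `min_score` is kept.
#' @param allowed_sem_types Optional character vector of semantic-type
#'   abbreviations.
#' @return The filtered records.
#' @export
filter_records <- function(records, min_score = 500L,
                           allowed_sem_types = NULL) {
  stopifnot(min_score >= 0L, min_score <= 1000L)
  keep <- records$score >= min_score
  if (!is.null(allowed_sem_types)) {
    keep <- keep & vapply(records$sem_types, function(st) {
      length(intersect(st, allowed_sem_types)) > 0L
    }, logical(1))
  }
  records[keep, , drop = FALSE]
}

#' Convert MMI records to character-span term mappings
#'
#' Each positional start/length pair becomes a half-open character span under
#' the configured offset base (0-based by default; MetaMap releases differ,
#' so the base is explicit rather than guessed). The mapped surface is read
#' from the document text; records whose span text matches none of the
#' trigger terms case-insensitively are flagged in `trigger_mismatch` but
#' still emitted.
#'
#' @param records A data.frame from [parse_mmi()] (typically filtered).
#' @param doc_text The document text the spans refer to.
#' @param offset_base 0 or 1; subtracted from the reported start.
#' @return A data.frame of term mappings: `doc_id`, `start`, `end` (0-based,
#'   half-open), `surface`, `cui`, `score`, `provenance` (`"mmi"`),
#'   `trigger_mismatch`.
#' @details A span that falls outside the document raises a `chv_span_error`
#'   naming the record.
#' @export
mmi_to_mappings <- function(records, doc_text, offset_base = 0L) {
  stopifnot(offset_base %in% c(0L, 1L))
  n <- nchar(doc_text)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    spans <- records$spans[[i]]
    for (j in seq_len(nrow(spans))) {
      start0 <- spans[j, 1L] - offset_base
      end0 <- start0 + spans[j, 2L]
      if (start0 < 0L || end0 > n) {
        chv_error(sprintf("record %s/%s: span (%d,%d) outside document of %d chars",
                          records$doc_id[i], records$cui[i],
                          spans[j, 1L], spans[j, 2L], n),
                  "chv_span_error")
      }
      surface <- substr(doc_text, start0 + 1L, end0)
      mism <- !(tolower(surface) %in% tolower(records$triggers[[i]]))
      rows[[length(rows) + 1L]] <-
        data.frame(doc_id = records$doc_id[i], start = start0, end = end0,
                   surface = surface, cui = records$cui[i],
                   score = records$score[i], provenance = "mmi",
                   trigger_mismatch = mism, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      cui = character(0), score = integer(0),
                      provenance = character(0), trigger_mismatch = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Expand predefined abbreviations before mapping
#'
#' Whole-token, case-sensitive replacement of short forms by their
#' expansions (e.g. `LV` by `left ventricle`), so that concept mapping sees
#' the full form of abbreviations the vocabulary covers only in expanded
#' form. Matching is case-sensitive on whole tokens to avoid expanding
#' common lowercase words, and tokens inside longer tokens (e.g. `LVEF`) are
#' never touched.
#'
#' @param text Document text.
#' @param abbrevs Named character vector (names are the single-token short
#'   forms) or a two-column data.frame (short form, expansion).
#' @return An object of class `chv_expansion`: a list with `text` (the
#'   expanded document) and `map` (a data.frame of replaced segments with
#'   0-based half-open spans in both coordinate systems). Use
#'   [original_span()] to translate expanded-text offsets back.
#' @export
expand_abbreviations <- function(text, abbrevs) {
  if (is.data.frame(abbrevs)) {
    abbrevs <- stats::setNames(as.character(abbrevs[[2L]]),
                               as.character(abbrevs[[1L]]))
  }
  stopifnot(is.character(abbrevs))
  if (length(abbrevs) && any(grepl("[[:space:]]", names(abbrevs)))) {
    chv_error("abbreviation short forms must be single tokens",
              "chv_config_error")
  }
  map <- data.frame(out_start = integer(0), out_end = integer(0),
                    in_start = integer(0), in_end = integer(0),
                    original = character(0), expansion = character(0),
                    stringsAsFactors = FALSE)
  if (!length(abbrevs)) {
    return(structure(list(text = text, map = map), class = "chv_expansion"))
  }
  toks <- tokenize_spans(text)
  hit <- toks$token %in% names(abbrevs)
  pieces <- character(0)
  cursor0 <- 0L
  delta <- 0L
  for (i in which(hit)) {
    exp_str <- unname(abbrevs[toks$token[i]])
    pieces <- c(pieces, substr(text, cursor0 + 1L, toks$start[i]))
    pieces <- c(pieces, exp_str)
    map <- rbind(map, data.frame(
      out_start = toks$start[i] + delta,
      out_end = toks$start[i] + delta + nchar(exp_str),
      in_start = toks$start[i], in_end = toks$end[i],
      original = toks$token[i], expansion = exp_str,
      stringsAsFactors = FALSE))
    delta <- delta + nchar(exp_str) - (toks$end[i] - toks$start[i])
    cursor0 <- toks$end[i]
  }
  pieces <- c(pieces, substr(text, cursor0 + 1L, nchar(text)))
  structure(list(text = paste(pieces, collapse = ""), map = map),
            class = "chv_expansion")
}

#' Translate an expanded-text span back to original-text offsets
#'
#' @param expansion A `chv_expansion` from [expand_abbreviations()].
#' @param start,end 0-based half-open span in the expanded text.
#' @return Integer vector `c(start, end)` in the original text. Spans that
#'   overlap an expansion are widened to cover the whole original short form.
#' @export
original_span <- function(expansion, start, end) {
  m <- expansion$map
  map_pos <- function(p, is_end) {
    inside <- which(p > m$out_start & p < m$out_end)
    if (length(inside)) {
      return(if (is_end) m$in_end[inside[1L]] else m$in_start[inside[1L]])
    }
    before <- m[m$out_end <= p, , drop = FALSE]
    shift <- sum((before$out_end - before$out_start) -
                   (before$in_end - before$in_start))
    p - shift
  }
  c(map_pos(start, FALSE), map_pos(end, TRUE))
}

#' Map a document with the built-in dictionary longest-match mapper
#'
#' A deterministic stand-in for an external concept mapper: scans token
#' n-grams from `max_tokens` down to 1, left to right; an n-gram whose
#' normalization is a known vocabulary surface yields one mapping per
#' matching CUI with score 1000. Tokens consumed by a longer match are not
#' re-matched at smaller n, so output spans are pairwise disjoint and sorted.
#' Tokenization splits on non-alphanumeric boundaries but keeps hyphenated
#' words whole; matching is case-insensitive via [normalize_term()].
#'
#' @param doc_text Document text.
#' @param index A `chv_index`.
#' @param max_tokens Longest n-gram considered (default 5).
#' @param doc_id Document identifier recorded in the mappings.
#' @return A data.frame of term mappings in the layout of
#'   [mmi_to_mappings()], with `provenance = "builtin"`.
#' @export
builtin_map <- function(doc_text, index, max_tokens = 5L, doc_id = "doc") {
  stopifnot(inherits(index, "chv_index"), max_tokens >= 1L)
  toks <- tokenize_spans(doc_text)
  n <- nrow(toks)
  rows <- list()
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (k in seq(min(max_tokens, n - i + 1L), 1L)) {
      j <- i + k - 1L
      s0 <- toks$start[i]
      e0 <- toks$end[j]
      key <- normalize_term(substr(doc_text, s0 + 1L, e0))
      cuis <- index$surfaces[[key]]
      if (!is.null(cuis)) {
        for (cui in cuis) {
          rows[[length(rows) + 1L]] <-
            data.frame(doc_id = doc_id, start = s0, end = e0,
                       surface = substr(doc_text, s0 + 1L, e0), cui = cui,
                       score = 1000L, provenance = "builtin",
                       trigger_mismatch = FALSE, stringsAsFactors = FALSE)
        }
        i <- j + 1L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      cui = character(0), score = integer(0),
                      provenance = character(0), trigger_mismatch = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
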