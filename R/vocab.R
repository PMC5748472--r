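# MRCONSO-dialect vocabulary files and the consumer-preferred-term index.

#' @name mrconso-fields
#' @title MRCONSO field order
#' @description Column order of the 18-field pipe-delimited RRF concept-names
#'   table: CUI, language, term status, lexical/string identifiers, preferred
#'   flag, atom identifier, source identifiers, source abbreviation (SAB),
#'   term type (TTY), source code, the term string (STR), and three trailing
#'   administrative fields.
#' @keywords internal
NULL

MRCONSO_FIELDS <- c("cui", "lat", "ts", "lui", "stt", "sui", "ispref", "aui",
                    "saui", "scui", "sdui", "sab", "tty", "code", "str",
                    "srl", "suppress", "cvf")

#' Parse MRCONSO-dialect vocabulary records
#'
#' Reads pipe-delimited RRF lines (18 fields, with or without a trailing
#' pipe) into a data frame with one row per record. Empty lines are skipped.
#'
#' @param lines Character vector of lines, or a single path to a UTF-8 file.
#' @return A data.frame with the 18 RRF columns (see [mrconso-fields]), all
#'   character.
#' @details Raises a `chv_format_error` naming the offending line when a line
#'   does not have 18 fields after trailing-pipe normalization, when a CUI
#'   does not match `C` + 7 digits, when a term string is empty, or when an
#'   AUI is duplicated within the input.
#' @examples
#' parse_mrconso(paste0("C0027540|ENG|P|L0|PF|S0|Y|A0000001||||CHV|PT|0000|",
#'                      "tissue death|0|N||"))
#' @export
parse_mrconso <- function(lines) {
  if (length(lines) == 1L && !grepl("|", lines, fixed = TRUE) &&
      file.exists(lines)) {
    lines <- readLines(lines, encoding = "UTF-8", warn = FALSE)
  }
  keep <- which(nzchar(trimws(lines)))
  empty <- data.frame(matrix(character(0), ncol = 18L,
                             dimnames = list(NULL, MRCONSO_FIELDS)),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)

  fields <- split_pipes(lines[keep])
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    # trailing-pipe dialect: one extra empty field after the 18th
    if (length(f) == 19L && f[19L] == "") f <- f[-19L]
    ln <- keep[i]
    if (length(f) != 18L) {
      chv_error(sprintf("line %d: expected 18 fields, found %d", ln, length(f)),
                "chv_format_error")
    }
    if (!is_valid_cui(f[1L])) {
      chv_error(sprintf("line %d: malformed CUI '%s'", ln, f[1L]),
                "chv_format_error")
    }
    if (!nzchar(trimws(f[15L]))) {
      chv_error(sprintf("line %d: empty term string (STR)", ln),
                "chv_format_error")
    }
    rows[[i]] <- f
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- MRCONSO_FIELDS
  dup <- duplicated(out$aui)
  if (any(dup)) {
    chv_error(sprintf("line %d: duplicate AUI '%s'",
                      keep[which(dup)[1L]], out$aui[which(dup)[1L]]),
              "chv_format_error")
  }
  rownames(out) <- NULL
  out
}

#' Serialize vocabulary records back to RRF lines
#'
#' @param rows A data.frame as returned by [parse_mrconso()].
#' @param trailing_pipe Append the conventional trailing pipe (default TRUE).
#' @return Character vector of pipe-delimited lines.
#' @export
format_mrconso <- function(rows, trailing_pipe = TRUE) {
  stopifnot(all(MRCONSO_FIELDS %in% names(rows)))
  lines <- do.call(paste, c(unname(as.list(rows[MRCONSO_FIELDS])), sep = "|"))
  if (trailing_pipe) lines <- paste0(lines, "|")
  lines
}

#' Build the consumer-preferred-term index
#'
#' Collects, for one vocabulary source, the preferred term of every concept
#' and a lookup table from normalized term surfaces to concept identifiers.
#'
#' The preferred term of a CUI is the STR of its `TTY == "PT"` rows within
#' the source. When a CUI carries more than one distinct preferred string
#' (a known idiosyncrasy of consumer-vocabulary releases), the row with the
#' lexicographically smallest AUI wins and the CUI is flagged in
#' `ambiguous_cuis`; the tie-break is order-independent, so permuting the
#' input rows never changes the index. If the source has no `PT` rows at all,
#' rows with `TS == "P"` and `ISPREF == "Y"` are used instead (term-type
#' conventions vary across vocabulary releases). All rows of the source,
#' preferred and synonym alike, contribute their normalized STR to the
#' surface lookup. CUIs present only as synonyms get no preferred entry and
#' are listed in `sy_only_cuis`.
#'
#' @param rows Parsed vocabulary records ([parse_mrconso()]).
#' @param source_label SAB of the consumer vocabulary (default `"CHV"`).
#' @param english_only Keep only `LAT == "ENG"` rows (default TRUE).
#' @return An object of class `chv_index` with elements `preferred` (named
#'   character vector, CUI to preferred string), `surfaces` (named list,
#'   normalized surface to character vector of CUIs), `ambiguous_cuis`,
#'   `sy_only_cuis` and `source_label`.
#' @details Raises a `chv_empty_index_error` when no rows carry the requested
#'   source label (the message distinguishes empty input from a source with
#'   no rows).
#' @export
build_index <- function(rows, source_label = "CHV", english_only = TRUE) {
  stopifnot(is.character(source_label), nzchar(source_label))
  if (english_only && nrow(rows)) rows <- rows[rows$lat == "ENG", , drop = FALSE]
  src <- rows[rows$sab == source_label, , drop = FALSE]
  if (!nrow(src)) {
    msg <- if (!nrow(rows)) {
      "cannot build index: no vocabulary rows were supplied"
    } else {
      sprintf("cannot build index: no rows with source label '%s'", source_label)
    }
    chv_error(msg, "chv_empty_index_error")
  }

  pt <- src[src$tty == "PT", , drop = FALSE]
  if (!nrow(pt)) pt <- src[src$ts == "P" & src$ispref == "Y", , drop = FALSE]

  preferred <- character(0)
  ambiguous <- character(0)
  if (nrow(pt)) {
    pt <- pt[order(pt$cui, pt$aui), , drop = FALSE]
    first <- !duplicated(pt$cui)
    preferred <- stats::setNames(pt$str[first], pt$cui[first])
    n_distinct <- tapply(pt$str, pt$cui, function(s) length(unique(s)))
    ambiguous <- sort(names(n_distinct)[n_distinct > 1L])
  }

  surf_keys <- normalize_term(src$str)
  ok <- nzchar(surf_keys)
  surfaces <- lapply(split(src$cui[ok], surf_keys[ok]),
                     function(x) sort(unique(x)))
  sy_only <- sort(setdiff(unique(src$cui), names(preferred)))

  structure(list(preferred = preferred,
                 surfaces = surfaces,
                 ambiguous_cuis = ambiguous,
                 sy_only_cuis = sy_only,
                 source_label = source_label),
            class = "chv_index")
}

#' @export
print.chv_index <- function(x, ...) {
  cat(sprintf(paste0("<chv_index> source=%s: %d concepts with a preferred ",
                     "term, %d surfaces, %d ambiguous, %d synonym-only\n"),
              x$source_label, length(x$preferred), length(x$surfaces),
              length(x$ambiguous_cuis), length(x$sy_only_cuis)))
  invisible(x)
}

#' Look up the preferred term of a concept
#'
#' @param index A `chv_index`.
#' @param cui Character vector of concept identifiers.
#' @return Character vector of preferred terms; `NA` for CUIs that are
#'   unknown or present only as synonyms (never an error).
#' @export
preferred_term <- function(index, cui) {
  stopifnot(inherits(index, "chv_index"))
  out <- unname(index$preferred[cui])
  as.character(out)
}

#' Persist and reload a preferred-term index
#'
#' Writes two tab-delimited files under `dir`: `preferred.tsv` (cui,
#' preferred term) and `surfaces.tsv` (normalized surface, cui; one row per
#' pair). A versioned header comment records the source label and the
#' ambiguous CUIs so the reloaded index is equivalent to the original.
#'
#' @param index A `chv_index`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "chv_index"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("#chv_index v1 source=%s ambiguous=%s sy_only=%s",
                 index$source_label,
                 paste(index$ambiguous_cuis, collapse = ","),
                 paste(index$sy_only_cuis, collapse = ","))
  pf <- file.path(dir, "preferred.tsv")
  writeLines(c(hdr, paste(names(index$preferred), index$preferred,
                          sep = "\t")), pf, useBytes = TRUE)
  sf <- file.path(dir, "surfaces.tsv")
  pairs <- unlist(lapply(names(index$surfaces), function(k) {
    paste(k, index$surfaces[[k]], sep = "\t")
  }))
  writeLines(c(hdr, pairs), sf, useBytes = TRUE)
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  pf <- file.path(dir, "preferred.tsv")
  sf <- file.path(dir, "surfaces.tsv")
  if (!file.exists(pf) || !file.exists(sf)) {
    chv_error(sprintf("no persisted index under '%s'", dir), "chv_config_error")
  }
  plines <- readLines(pf, encoding = "UTF-8", warn = FALSE)
  hdr <- plines[1L]
  if (!startsWith(hdr, "#chv_index v1")) {
    chv_error("unrecognized index file version", "chv_format_error")
  }
  get_attr <- function(key) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]*", key), hdr))
    sub(sprintf("^%s=", key), "", m)
  }
  split_csv <- function(x) if (!nzchar(x)) character(0) else strsplit(x, ",")[[1]]
  pbody <- plines[-1L][nzchar(plines[-1L])]
  pparts <- strsplit(pbody, "\t", fixed = TRUE)
  preferred <- stats::setNames(vapply(pparts, `[`, "", 2L),
                               vapply(pparts, `[`, "", 1L))
  slines <- readLines(sf, encoding = "UTF-8", warn = FALSE)[-1L]
  slines <- slines[nzchar(slines)]
  sparts <- strsplit(slines, "\t", fixed = TRUE)
  skey <- vapply(sparts, `[`, "", 1L)
  scui <- vapply(sparts, `[`, "", 2L)
  surfaces <- lapply(split(scui, skey), function(x) sort(unique(x)))
  structure(list(preferred = preferred,
                 surfaces = surfaces,
                 ambiguous_cuis = split_csv(get_attr("ambiguous")),
                 sy_only_cuis = split_csv(get_attr("sy_only")),
                 source_label = get_attr("source")),
            class = "chv_index")
}
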