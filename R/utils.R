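# Shared helpers: error conditions, term normalization, pipe splitting.

chv_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "chv_error"), call = call))
}

#' Normalize a term surface for lookup
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' leading/trailing whitespace and enclosing punctuation. Idempotent. Applied
#' to lookup keys only; stored preferred terms keep their original casing.
#'
#' @param s Character vector.
#' @return Character vector of normalized surfaces.
#' @examples
#' normalize_term("  Tissue  Death ")
#' normalize_term("[LV]")
#' @export
normalize_term <- function(s) {
  s <- tolower(s)
  s <- gsub("[[:space:]]+", " ", s)
  s <- trimws(s)
  s <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", s)
  trimws(s)
}

# Split pipe-delimited lines keeping interior empty fields. Returns a list of
# character vectors; a single trailing pipe (RRF dialect) is tolerated by the
# callers, which drop one trailing empty field.
split_pipes <- function(lines) {
  n_seps <- nchar(lines) - nchar(gsub("|", "", lines, fixed = TRUE))
  fields <- strsplit(lines, "|", fixed = TRUE)
  Map(function(f, n) c(f, rep("", n + 1L - length(f))), fields, n_seps)
}

is_valid_cui <- function(cui) grepl("^C[0-9]{7}$", cui)

# Tokenize text keeping hyphenated words whole; returns a data.frame with
# 0-based half-open character spans.
tokenize_spans <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      token = character(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(start = start, end = end,
             token = substring(text, start + 1L, end),
             stringsAsFactors = FALSE)
}

# Simple word tokens for similarity classification (hyphens split).
word_tokens <- function(s) {
  toks <- regmatches(tolower(s), gregexpr("[a-z0-9]+", tolower(s)))[[1]]
  toks[nzchar(toks)]
}
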