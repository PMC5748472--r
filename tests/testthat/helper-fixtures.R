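# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

rrf_fixture_line <- function(cui, str, aui, sab = "CHV", tty = "PT",
                             ispref = "Y", ts = "P", lat = "ENG") {
  paste(cui, lat, ts, "L0000001", "PF", "S0000001", ispref, aui, "", "", "",
        sab, tty, "0001", str, "0", "N", "", sep = "|")
}

# two-concept vocabulary: one with PT + SY, one PT-only
mini_vocab_rows <- function() {
  parse_mrconso(c(
    rrf_fixture_line("C0027540", "tissue death", "A0000001"),
    rrf_fixture_line("C0027540", "necrosis", "A0000002", tty = "SY",
                     ispref = "N", ts = "S"),
    rrf_fixture_line("C0229664", "lateral", "A0000003")
  ))
}

mini_index <- function() build_index(mini_vocab_rows())

mmi_fixture_line <- function(doc = "R1", score = 812, name = "Necrosis",
                             cui = "C0027540", sem = "[patf]",
                             trig = '["necrosis"-tx-1-"necrosis"-noun-0]',
                             pos = "117/8") {
  paste(doc, "MMI", score, name, cui, sem, trig, "TX", pos, "", sep = "|")
}

# enumerate all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# independent brute-force oracle for phrase similarity: enumerate all token
# bijections instead of running the matching algorithm
brute_force_similar <- function(a, b) {
  stop_set <- c("a", "an", "the", "of", "and", "or", "to", "in")
  tok <- function(s) {
    t <- regmatches(tolower(s), gregexpr("[a-z0-9]+", tolower(s)))[[1]]
    t[!(t %in% stop_set)]
  }
  ta <- tok(a)
  tb <- tok(b)
  if (length(ta) != length(tb)) return(FALSE)
  for (perm in all_perms(length(ta))) {
    if (all(mapply(same_stem_variant, ta, tb[perm]))) return(TRUE)
  }
  FALSE
}
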