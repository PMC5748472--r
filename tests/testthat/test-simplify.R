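# Overlap resolution and preferred-term replacement.

mk_map <- function(start, end, cui, score = 1000L, doc_id = "d1",
                   surface = strrep("x", end - start)) {
  data.frame(doc_id = doc_id, start = start, end = end, surface = surface,
             cui = cui, score = score, provenance = "builtin",
             trigger_mismatch = FALSE, stringsAsFactors = FALSE)
}

test_that("resolve_overlaps applies the longer-span / start / score / cui priority", {
  nested <- rbind(mk_map(0L, 12L, "C0000001"), mk_map(6L, 12L, "C0000002"))
  expect_equal(resolve_overlaps(nested)$start, 0L)
  expect_equal(resolve_overlaps(nested[2:1, ])$start, 0L)

  disjoint <- rbind(mk_map(10L, 14L, "C0000001"), mk_map(0L, 4L, "C0000002"))
  expect_equal(resolve_overlaps(disjoint)$start, c(0L, 10L))

  same_span <- rbind(mk_map(0L, 5L, "C0000010"), mk_map(0L, 5L, "C0000002"))
  expect_equal(resolve_overlaps(same_span)$cui, "C0000002")

  higher_score <- rbind(mk_map(0L, 5L, "C0000009", score = 700L),
                        mk_map(0L, 5L, "C0000005", score = 900L))
  expect_equal(resolve_overlaps(higher_score)$cui, "C0000005")

  # determinism under input permutation
  set.seed(5)
  pool <- do.call(rbind, lapply(1:12, function(i) {
    s <- sample(0:40, 1)
    mk_map(s, s + sample(3:9, 1), sprintf("C%07d", sample(99, 1)),
           score = sample(500:1000, 1))
  }))
  ref <- resolve_overlaps(pool)
  for (i in 1:10) {
    expect_equal(resolve_overlaps(pool[sample(nrow(pool)), ]), ref)
  }
})

test_that("apply_replacements substitutes the preferred term in brackets", {
  idx <- mini_index()
  text <- "Patchy necrosis is seen."
  m <- mk_map(7L, 15L, "C0027540", surface = "necrosis")
  sd <- apply_replacements(text, m, idx)
  expect_equal(sd$simplified_text, "Patchy [tissue death] is seen.")
  expect_equal(sd$replacements$action, "replaced")
  expect_equal(sd$replacements$replacement, "tissue death")
  # output span covers the bracketed written text
  expect_equal(substr(sd$simplified_text,
                      sd$replacements$out_start + 1L,
                      sd$replacements$out_end),
               "[tissue death]")
  expect_equal(revert_simplification(sd), text)

  # without brackets
  sd2 <- apply_replacements(text, m, idx,
                            replacement_options(mark_brackets = FALSE))
  expect_equal(sd2$simplified_text, "Patchy tissue death is seen.")
})

test_that("no mappings leaves the text untouched; unknown concepts are logged", {
  idx <- mini_index()
  text <- "Nothing to do here."
  sd <- apply_replacements(text, mk_map(0L, 0L, "C0000001")[0, ], idx)
  expect_equal(sd$simplified_text, text)
  expect_equal(nrow(sd$replacements), 0L)

  m <- mk_map(0L, 7L, "C7654321", surface = "Nothing")
  sd2 <- apply_replacements(text, m, idx)
  expect_equal(sd2$simplified_text, text)
  expect_equal(sd2$replacements$action, "skipped_no_pt")
  expect_equal(sd2$unmapped_spans$surface, "Nothing")
})

test_that("the stem guard records same-stem pairs as skipped_similar", {
  rows <- parse_mrconso(c(
    rrf_fixture_line("C0205400", "thickened", "A0000001"),
    rrf_fixture_line("C0205400", "thickening", "A0000002", tty = "SY",
                     ispref = "N", ts = "S")
  ))
  idx <- build_index(rows)
  text <- "Thickening of the wall."
  m <- mk_map(0L, 10L, "C0205400", surface = "Thickening")
  guarded <- apply_replacements(text, m, idx,
                                replacement_options(skip_if_same_stem = TRUE))
  expect_equal(guarded$simplified_text, text)
  expect_equal(guarded$replacements$action, "skipped_similar")

  # defaults replace it, transferring the leading capital
  default <- apply_replacements(text, m, idx)
  expect_equal(default$simplified_text, "[Thickened] of the wall.")
  # with the guard on, no emitted replacement pair is classified similar
  reps <- guarded$replacements[guarded$replacements$action == "replaced", ]
  if (nrow(reps)) {
    expect_false(any(mapply(classify_similarity, reps$original,
                            reps$replacement) == "similar"))
  }
})

test_that("acronym originals transfer no casing to the expansion", {
  rows <- parse_mrconso(rrf_fixture_line("C0023211", "left ventricle",
                                         "A0000001"))
  idx <- build_index(rows)
  sd <- apply_replacements("LV normal.", mk_map(0L, 2L, "C0023211",
                                                surface = "LV"), idx)
  expect_equal(sd$simplified_text, "[left ventricle] normal.")
})

test_that("adjust_article follows the vowel-letter rule and preserves capitalization", {
  expect_equal(adjust_article("a", "effusion"), "an")
  expect_equal(adjust_article("an", "mass"), "a")
  expect_equal(adjust_article("the", "effusion"), "the")
  expect_equal(adjust_article("A", "effusion"), "An")
  expect_equal(adjust_article("An", "mass"), "A")
  expect_equal(adjust_article("a", "mass"), "a")
})

test_that("articles are adjusted in context and the adjustment is reversible", {
  rows <- parse_mrconso(c(
    rrf_fixture_line("C0013687", "effusion", "A0000001"),
    rrf_fixture_line("C0013687", "free fluid", "A0000002", tty = "SY",
                     ispref = "N", ts = "S")
  ))
  idx <- build_index(rows)
  text <- "There is a free fluid collection."
  m <- mk_map(11L, 21L, "C0013687", surface = "free fluid")
  sd <- apply_replacements(text, m, idx)
  expect_equal(sd$simplified_text, "There is an [effusion] collection.")
  expect_equal(nrow(sd$articles), 1L)
  expect_equal(revert_simplification(sd), text)

  # with article adjustment off, the article is untouched
  sd2 <- apply_replacements(text, m, idx,
                            replacement_options(adjust_articles = FALSE))
  expect_equal(sd2$simplified_text, "There is a [effusion] collection.")
})

test_that("overlapping mappings are rejected as a precondition violation", {
  idx <- mini_index()
  mm <- rbind(mk_map(0L, 8L, "C0027540", surface = "necrosis"),
              mk_map(4L, 10L, "C0229664", surface = "osis s"))
  expect_error(apply_replacements("necrosis seen", mm, idx),
               class = "chv_overlap_error")
})

test_that("replacement is reversible and length accounting balances on synthetic documents", {
  cfg <- generator_config(n_concepts = 80, n_reports = 40,
                          terms_per_report = c(3, 7), seed = 99)
  syn <- synth_corpus(cfg)
  idx <- build_index(parse_mrconso(syn$vocab$rrf_lines))
  for (id in names(syn$reports)) {
    text <- syn$reports[[id]]
    m <- resolve_overlaps(builtin_map(text, idx, doc_id = id))
    sd <- apply_replacements(text, m, idx, doc_id = id)
    expect_identical(revert_simplification(sd), text)

    reps <- sd$replacements[sd$replacements$action == "replaced", ]
    delta_rep <- sum((reps$out_end - reps$out_start) -
                       (reps$in_end - reps$in_start))
    delta_art <- sum((sd$articles$out_end - sd$articles$out_start) -
                       (sd$articles$in_end - sd$articles$in_start))
    expect_equal(nchar(sd$simplified_text) - nchar(text),
                 delta_rep + delta_art)

    # deterministic
    sd_again <- apply_replacements(text, m, idx, doc_id = id)
    expect_identical(sd_again$simplified_text, sd$simplified_text)
  }
})
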