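# Stemming, similarity classification, statistics, categorization, and
# corpus evaluation.

test_that("stem_token reproduces the published suffix-stripping behavior", {
  # frozen vectors computed with the original algorithm's rule set
  cases <- c(caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
             agreed = "agre", plastered = "plaster", motoring = "motor",
             hopping = "hop", tanned = "tan", falling = "fall",
             filing = "file", happy = "happi", sky = "sky",
             relational = "relat", conditional = "condit",
             electrical = "electr", hopefulness = "hope",
             adjustable = "adjust", replacement = "replac",
             adoption = "adopt", rate = "rate", cease = "ceas",
             controll = "control", roll = "roll")
  expect_equal(stem_token(names(cases)), unname(cases))
  # inflectional variants used in the similarity rule share a stem
  expect_equal(stem_token("thickening"), stem_token("thickened"))
  expect_equal(stem_token("lateral"), stem_token("lateral"))
  # unrelated words keep distinct stems
  expect_false(stem_token("necrosis") == stem_token("death"))
})

test_that("same_stem_variant accepts stem matches and long common prefixes", {
  # common prefix "abdom" (5) reaches max(4, ceil(0.6*7)) = 5
  expect_true(same_stem_variant("abdominal", "abdomen"))
  expect_true(same_stem_variant("abdomen", "abdominal"))
  expect_true(same_stem_variant("x", "x"))
  # prefix "post" (4) falls short of max(4, ceil(0.6*9)) = 6
  expect_false(same_stem_variant("posterior", "postcontrast"))
  expect_false(same_stem_variant("postcontrast", "posterior"))
  # pure stem match without a long prefix
  expect_true(same_stem_variant("thickening", "thickened"))
})

test_that("classify_similarity reproduces the reference classification examples", {
  expect_equal(classify_similarity("Lateral", "Lateral"), "similar")
  expect_equal(classify_similarity("Thickening", "Thickened"), "similar")
  expect_equal(classify_similarity("Abdominal wall", "Wall of abdomen"),
               "similar")
  expect_equal(classify_similarity("Ventricle", "Heart ventricle"),
               "different")
  expect_equal(classify_similarity("Necrosis", "Tissue death"), "different")
  expect_equal(classify_similarity("free fluid", "effusion"), "different")
  expect_error(classify_similarity("the of", "term"),
               class = "chv_classification_error")
})

test_that("classify_similarity is symmetric", {
  pairs <- list(c("Lateral", "Lateral"), c("Thickening", "Thickened"),
                c("Abdominal wall", "Wall of abdomen"),
                c("Ventricle", "Heart ventricle"),
                c("Necrosis", "Tissue death"),
                c("renal cortex", "outer layer of the kidney"))
  for (p in pairs) {
    expect_equal(classify_similarity(p[1], p[2]),
                 classify_similarity(p[2], p[1]))
  }
})

test_that("the matching-based phrase decision agrees with brute-force bijection enumeration", {
  set.seed(21)
  words <- c("wall", "walls", "abdomen", "abdominal", "heart", "ventricle",
             "cortex", "cortical", "renal", "thicken", "thickening")
  for (i in 1:120) {
    n1 <- sample(1:4, 1)
    n2 <- sample(1:4, 1)
    a <- paste(sample(words, n1, replace = TRUE), collapse = " ")
    b <- paste(sample(words, n2, replace = TRUE), collapse = " ")
    got <- classify_similarity(a, b) == "similar"
    expect_equal(got, brute_force_similar(a, b), info = paste(a, "|", b))
  }
  # duplicated tokens need equal counts on both sides
  expect_equal(classify_similarity("wall wall abdomen", "abdominal wall wall"),
               "similar")
  expect_equal(classify_similarity("wall wall", "wall abdomen"), "different")
})

test_that("coverage and similarity follow their equations with the stated rounding", {
  expect_equal(content_coverage(320, 378), 84.66)
  expect_equal(content_coverage(50, 50), 100)
  expect_equal(content_coverage(0, 10), 0)
  expect_error(content_coverage(0, 0), class = "chv_undefined_statistic_error")

  expect_equal(lexical_similarity(52, 68), 76.47)
  expect_equal(lexical_similarity(505, 695, decimals = 1, mode = "floor"),
               72.6)
  expect_equal(lexical_similarity(0, 9), 0)
  expect_error(lexical_similarity(0, 0),
               class = "chv_undefined_statistic_error")

  expect_equal(round_pct(84.656, 2, "nearest"), 84.66)
  expect_equal(round_pct(72.662, 1, "floor"), 72.6)
  expect_equal(round_pct(50.0, 0, "nearest"), 50)
  expect_equal(round_pct(2.345, 2, "nearest"), 2.35) # half-up
})

test_that("summary_from_counts derives totals and percentages from class counts", {
  s <- summary_from_counts(505, 190, 97, decimals = 1)
  expect_equal(s$total, 792)
  expect_equal(s$covered, 695)
  expect_equal(s$similar_of_total_pct, 63.8)
  expect_equal(s$different_of_total_pct, 24)
  expect_equal(s$missing_of_total_pct, 12.2)
  s4 <- summary_from_counts(505, 190, 0, decimals = 1, mode = "floor")
  expect_equal(s4$similarity_pct, 72.6)
  expect_equal(s4$different_pct, 27.3)
})

test_that("categorize_missing honors overrides and the fixed category order", {
  lex <- default_missing_lexicons()
  expect_equal(categorize_missing("midthoracic", lex), "anatomy")
  expect_equal(categorize_missing("anteroposterior", lex),
               "technique_projection")
  expect_equal(categorize_missing("post-contrast", lex),
               "technique_projection")
  expect_equal(categorize_missing("tracheomegaly", lex),
               "anatomical_description")
  expect_equal(categorize_missing("zzzunknown", lex), "uncategorized")
  expect_equal(categorize_missing("midthoracic", lex, override = "physiology"),
               "physiology")
})

test_that("evaluate_corpus applies counting rules and the two equations on a toy report", {
  idx <- mini_index()
  maps <- rbind(
    data.frame(doc_id = "r1", start = 0L, end = 8L, surface = "necrosis",
               cui = "C0027540", score = 1000L, provenance = "builtin",
               trigger_mismatch = FALSE, stringsAsFactors = FALSE),
    data.frame(doc_id = "r1", start = 20L, end = 27L, surface = "lateral",
               cui = "C0229664", score = 1000L, provenance = "builtin",
               trigger_mismatch = FALSE, stringsAsFactors = FALSE))
  ann <- data.frame(
    doc_id = "r1",
    surface = c("necrosis", "lateral", "tracheomegaly"),
    stringsAsFactors = FALSE)
  ev <- evaluate_corpus(ann, maps, idx)
  expect_equal(ev$overall$total, 3L)
  expect_equal(ev$overall$covered, 2L)
  expect_equal(ev$overall$coverage_pct, 66.67)
  expect_equal(ev$overall$similarity_pct, 50)
  got <- ev$terms[ev$terms$surface == "necrosis", ]
  expect_equal(got$similarity, "different")
  expect_equal(ev$terms[ev$terms$surface == "lateral", ]$similarity,
               "similar")
  miss <- ev$terms[ev$terms$status == "missing", ]
  expect_equal(miss$surface, "tracheomegaly")
  expect_equal(miss$category, "anatomical_description")

  # simple-English exclusion: excluded terms leave the totals unchanged
  ann2 <- rbind(ann, data.frame(doc_id = "r1", surface = "patient"))
  ev2 <- evaluate_corpus(ann2, maps, idx,
                         policy = counting_policy(exclusion_list = "patient"))
  expect_equal(ev2$overall$total, 3L)
  expect_equal(sum(ev2$terms$status == "excluded"), 1L)

  # per-report dedup: a term listed twice is counted once
  ann3 <- rbind(ann, data.frame(doc_id = "r1", surface = "Necrosis"))
  ev3 <- evaluate_corpus(ann3, maps, idx)
  expect_equal(ev3$overall$total, 3L)

  # the same surface in another report counts again
  ann4 <- rbind(ann, data.frame(doc_id = "r2", surface = "necrosis"))
  maps4 <- rbind(maps, within(maps[1, ], doc_id <- "r2"))
  ev4 <- evaluate_corpus(ann4, maps4, idx)
  expect_equal(ev4$overall$total, 4L)

  expect_error(evaluate_corpus(ann[0, ], maps, idx),
               class = "chv_undefined_statistic_error")
  expect_error(evaluate_corpus(ann, maps, idx, doc_ids = "other_doc"),
               class = "chv_reference_error")
})

test_that("an abbreviation written once in full and once short counts as two terms", {
  rows <- parse_mrconso(rrf_fixture_line("C0023211", "left ventricle",
                                         "A0000001"))
  idx <- build_index(rows)
  maps <- data.frame(doc_id = "r1", start = 0L, end = 14L,
                     surface = "left ventricle", cui = "C0023211",
                     score = 1000L, provenance = "builtin",
                     trigger_mismatch = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(doc_id = "r1", surface = c("left ventricle", "LV"),
                    stringsAsFactors = FALSE)
  pol <- counting_policy(abbreviation_pairs = data.frame(
    full = "left ventricle", abbr = "LV"))
  ev <- evaluate_corpus(ann, maps, idx, policy = pol)
  expect_equal(ev$overall$total, 2L)
  expect_equal(ev$overall$covered, 1L)
  expect_equal(ev$terms[ev$terms$surface == "LV", ]$status, "missing")
})

test_that("pooled coverage equals the total-weighted mean of per-report coverages", {
  cfg <- generator_config(n_concepts = 100, n_reports = 12,
                          terms_per_report = c(6, 12), seed = 17)
  syn <- synth_corpus(cfg)
  idx <- build_index(parse_mrconso(syn$vocab$rrf_lines))
  maps <- do.call(rbind, lapply(names(syn$reports), function(id) {
    resolve_overlaps(builtin_map(syn$reports[[id]], idx, doc_id = id))
  }))
  ev <- evaluate_corpus(syn$annotations, maps, idx)
  per_doc <- split(ev$terms[ev$terms$counted, ], ev$terms$doc_id[ev$terms$counted])
  weighted <- sum(vapply(per_doc, function(d) sum(d$status == "covered"),
                         0)) / sum(vapply(per_doc, nrow, 0L))
  expect_equal(ev$overall$coverage_pct, round_pct(weighted * 100, 2),
               tolerance = 1e-9)
  # partition invariants
  expect_equal(ev$overall$covered + ev$overall$missing, ev$overall$total)
  expect_equal(ev$overall$similar + ev$overall$different, ev$overall$covered)
  expect_equal(sum(ev$missing_by_category$count), ev$overall$missing)
})
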