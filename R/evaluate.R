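# Evaluation of a simplified corpus: stem-based lexical-similarity
# classification, content coverage, missing-concept categorization, and
# per-modality aggregation.

.similarity_stopwords <- c("a", "an", "the", "of", "and", "or", "to", "in")

#' Same-stem variant test for single tokens
#'
#' Two tokens are variants of one another when their Porter stems are equal,
#' or when their lowercased longest common prefix reaches
#' `max(4, ceiling(0.6 * nchar(shorter)))` characters. The prefix fallback
#' admits derivational pairs the stemmer separates (e.g. *abdominal* /
#' *abdomen*, common prefix "abdom" of length 5) while rejecting short
#' accidental prefixes (*posterior* / *postcontrast* share only "post").
#' Symmetric.
#'
#' @param w1,w2 Single tokens.
#' @return Logical.
#' @export
same_stem_variant <- function(w1, w2) {
  w1 <- tolower(w1)
  w2 <- tolower(w2)
  if (stem_token(w1) == stem_token(w2)) return(TRUE)
  shorter <- min(nchar(w1), nchar(w2))
  threshold <- max(4L, ceiling(0.6 * shorter))
  if (shorter < threshold) return(FALSE)
  lcp <- 0L
  for (i in seq_len(shorter)) {
    if (substr(w1, i, i) != substr(w2, i, i)) break
    lcp <- i
  }
  lcp >= threshold
}

# Perfect bipartite matching between token sets under a compatibility
# matrix, via Kuhn's augmenting-path algorithm.
.perfect_matching_exists <- function(compat) {
  n <- nrow(compat)
  if (n != ncol(compat)) return(FALSE)
  if (n == 0L) return(TRUE)
  match_right <- rep(0L, n)
  try_kuhn <- function(u, seen) {
    for (v in seq_len(n)) {
      if (compat[u, v] && !seen[v]) {
        seen[v] <- TRUE
        if (match_right[v] == 0L) {
          match_right[v] <<- u
          return(TRUE)
        }
        prev <- match_right[v]
        match_right[v] <<- u
        if (try_kuhn(prev, seen)) return(TRUE)
        match_right[v] <<- prev
      }
    }
    FALSE
  }
  for (u in seq_len(n)) {
    if (!try_kuhn(u, rep(FALSE, n))) return(FALSE)
  }
  TRUE
}

#' Classify the lexical similarity of a term and its preferred term
#'
#' A pair is *similar* when, after lowercasing, tokenizing and dropping a
#' minimal stopword list (`a an the of and or to in`), a perfect one-to-one
#' matching exists between the two token multisets under
#' [same_stem_variant()]; otherwise *different*. Thus a preferred term that
#' paraphrases the same content words ("wall of abdomen" for "abdominal
#' wall") is similar, while one that adds a content word ("heart ventricle"
#' for "ventricle") or substitutes unrelated stems ("tissue death" for
#' "necrosis") is different. Symmetric in its arguments.
#'
#' @param original,preferred Non-empty term strings.
#' @return `"similar"` or `"different"`.
#' @details Raises a `chv_classification_error` when either string has no
#'   tokens left after stopword removal.
#' @examples
#' classify_similarity("Abdominal wall", "Wall of abdomen")
#' classify_similarity("Necrosis", "Tissue death")
#' @export
classify_similarity <- function(original, preferred) {
  t1 <- setdiff_keepdup(word_tokens(original), .similarity_stopwords)
  t2 <- setdiff_keepdup(word_tokens(preferred), .similarity_stopwords)
  if (!length(t1) || !length(t2)) {
    chv_error("term is empty after stopword removal", "chv_classification_error")
  }
  if (length(t1) != length(t2)) return("different")
  compat <- outer(seq_along(t1), seq_along(t2),
                  Vectorize(function(i, j) same_stem_variant(t1[i], t2[j])))
  if (.perfect_matching_exists(compat)) "similar" else "different"
}

# drop stopwords but keep duplicate content tokens (multiset semantics)
setdiff_keepdup <- function(x, drop) x[!(x %in% drop)]

#' Round a percentage for reporting
#'
#' Two conventions are exposed because published percentage tables mix them:
#' `nearest` is half-up rounding, `floor` truncates toward zero.
#'
#' @param x Non-negative numeric vector.
#' @param decimals Number of decimals (>= 0).
#' @param mode `"nearest"` (half-up) or `"floor"` (truncation).
#' @return Rounded numeric vector.
#' @examples
#' round_pct(84.656, 2, "nearest")
#' round_pct(72.662, 1, "floor")
#' @export
round_pct <- function(x, decimals = 2L, mode = c("nearest", "floor")) {
  mode <- match.arg(mode)
  stopifnot(decimals >= 0L)
  f <- 10^decimals
  if (mode == "nearest") {
    floor(x * f + 0.5 + 1e-9) / f
  } else {
    trunc(x * f + 1e-9) / f
  }
}

#' Content coverage percentage
#'
#' `covered * 100 / total`, the share of evaluated terms that map to a
#' concept of the target vocabulary.
#'
#' @param covered,total Counts with `0 <= covered <= total`, `total > 0`.
#' @param decimals,mode Passed to [round_pct()].
#' @return Percentage.
#' @details `total == 0` raises a `chv_undefined_statistic_error`.
#' @examples
#' content_coverage(320, 378)
#' @export
content_coverage <- function(covered, total, decimals = 2L, mode = "nearest") {
  if (total == 0) {
    chv_error("content coverage undefined for zero evaluated terms",
              "chv_undefined_statistic_error")
  }
  stopifnot(covered >= 0, covered <= total)
  round_pct(covered * 100 / total, decimals, mode)
}

#' Lexical similarity percentage
#'
#' `similar * 100 / covered`, the share of covered terms whose preferred
#' term is the same word, a same-stem variant, or a paraphrase of the same
#' words.
#'
#' @param similar,covered Counts with `0 <= similar <= covered`,
#'   `covered > 0`.
#' @param decimals,mode Passed to [round_pct()].
#' @return Percentage.
#' @details `covered == 0` raises a `chv_undefined_statistic_error`.
#' @examples
#' lexical_similarity(52, 68)
#' lexical_similarity(505, 695, decimals = 1, mode = "floor")
#' @export
lexical_similarity <- function(similar, covered, decimals = 2L,
                               mode = "nearest") {
  if (covered == 0) {
    chv_error("lexical similarity undefined for zero covered terms",
              "chv_undefined_statistic_error")
  }
  stopifnot(similar >= 0, similar <= covered)
  round_pct(similar * 100 / covered, decimals, mode)
}

#' Derive summary statistics from class counts
#'
#' Applies the coverage and similarity equations to externally obtained
#' counts of similar, different and missing terms (e.g. a published summary
#' table), returning the derived totals and percentages.
#'
#' @param similar,different,missing Non-negative counts.
#' @param decimals,mode Passed to [round_pct()].
#' @return A list with `total`, `covered`, `coverage_pct`, `similarity_pct`,
#'   `different_pct`, and the share of each class of the total
#'   (`similar_of_total_pct`, `different_of_total_pct`,
#'   `missing_of_total_pct`).
#' @export
summary_from_counts <- function(similar, different, missing,
                                decimals = 2L, mode = "nearest") {
  covered <- similar + different
  total <- covered + missing
  list(total = total,
       covered = covered,
       coverage_pct = content_coverage(covered, total, decimals, mode),
       similarity_pct = lexical_similarity(similar, covered, decimals, mode),
       different_pct = round_pct(different * 100 / covered, decimals, mode),
       similar_of_total_pct = round_pct(similar * 100 / total, decimals, mode),
       different_of_total_pct = round_pct(different * 100 / total, decimals, mode),
       missing_of_total_pct = round_pct(missing * 100 / total, decimals, mode))
}

.missing_categories <- c("anatomy", "anatomical_description",
                         "technique_projection", "physiology")

#' Default keyword lexicons for missing-concept categorization
#'
#' Small seed lists for the four categories of concepts a consumer
#' vocabulary typically fails to cover in radiology text: human anatomical
#' structures and regions, anatomical descriptions and pathological
#' variations, radiology techniques and projections, and physiology-related
#' terms.
#'
#' @return Named list of character vectors in fixed category order.
#' @export
default_missing_lexicons <- function() {
  list(
    anatomy = c("disc", "thorac", "axial", "cervic", "lumbar", "crani",
                "vertebr"),
    anatomical_description = c("heterogen", "megaly", "trophy", "plasia",
                               "ectasia"),
    technique_projection = c("contrast", "anteroposterior", "projection",
                             "weighted", "sagittal", "coronal", "doppler"),
    physiology = c("metabolic", "rhythm", "perfusion", "systolic",
                   "diastolic")
  )
}

#' Categorize a term the vocabulary does not cover
#'
#' An explicit override always wins. Otherwise categories are tried in the
#' fixed order anatomy, anatomical_description, technique_projection,
#' physiology; a lexicon entry matches when it equals a token of the
#' normalized surface, when it is a prefix or suffix of the surface, or —
#' for entries of at least 4 characters — when it occurs inside a token
#' (so a lexicon stem like `thorac` captures `midthoracic`).
#'
#' @param surface Non-empty term string.
#' @param lexicons Named list of keyword vectors, as
#'   [default_missing_lexicons()].
#' @param override Optional category name; returned as-is when present.
#' @return One of the four category names or `"uncategorized"`.
#' @export
categorize_missing <- function(surface, lexicons = default_missing_lexicons(),
                               override = NULL) {
  if (!is.null(override) && !is.na(override) && nzchar(override)) {
    return(override)
  }
  stopifnot(nzchar(surface))
  norm <- normalize_term(surface)
  toks <- word_tokens(norm)
  for (cat in .missing_categories) {
    lex <- lexicons[[cat]]
    if (is.null(lex)) next
    for (e in lex) {
      hit <- e %in% toks || startsWith(norm, e) || endsWith(norm, e) ||
        (nchar(e) >= 4L && any(grepl(e, toks, fixed = TRUE)))
      if (hit) return(cat)
    }
  }
  "uncategorized"
}

#' Term counting policy
#'
#' @param exclusion_list Normalized simple-English surfaces that are not
#'   counted at all (recorded with status `excluded`), e.g. "patient" or
#'   "right side".
#' @param abbreviation_pairs Optional two-column data.frame (full form,
#'   abbreviation) of pairs counted as two distinct terms. Distinct surfaces
#'   are never merged by the per-report deduplication, so the pairs serve as
#'   an audited declaration rather than a switch.
#' @return A list of class `chv_counting_policy`.
#' @export
counting_policy <- function(exclusion_list = character(0),
                            abbreviation_pairs = NULL) {
  exclusion_list <- normalize_term(as.character(exclusion_list))
  if (!is.null(abbreviation_pairs)) {
    stopifnot(is.data.frame(abbreviation_pairs),
              ncol(abbreviation_pairs) >= 2L)
    if (any(normalize_term(abbreviation_pairs[[1L]]) ==
            normalize_term(abbreviation_pairs[[2L]]))) {
      chv_error("abbreviation pairs must be distinct strings",
                "chv_config_error")
    }
  }
  structure(list(dedup_scope = "per_report",
                 exclusion_list = exclusion_list,
                 abbreviation_pairs = abbreviation_pairs),
            class = "chv_counting_policy")
}

#' Evaluate an annotated corpus
#'
#' Takes the annotated terms of interest per report plus the concept
#' mappings and the preferred-term index, and produces per-term records and
#' an aggregated summary. Excluded terms (exclusion list or
#' `include_flag == FALSE`) are not counted in totals; the remaining terms
#' are deduplicated per report by normalized surface (a full form and its
#' abbreviation are distinct surfaces and thus both counted). A term is
#' *covered* when a mapping with a preferred term exists for its surface in
#' its report, in which case the similarity of (surface, preferred term) is
#' classified; otherwise it is *missing* and categorized. The summary
#' reports counts and both pooled percentages and unweighted group-average
#' percentages (per imaging modality, say).
#'
#' @param annotations data.frame with columns `doc_id`, `surface`, optional
#'   `include_flag` (default TRUE), `category_override`, `group`.
#' @param mappings data.frame of term mappings for the corpus (may be empty).
#' @param index A `chv_index`.
#' @param policy A [counting_policy()].
#' @param groups Optional named character vector mapping `doc_id` to a group
#'   label; used when `annotations` has no `group` column.
#' @param doc_ids Optional vector of known document ids; an annotation for a
#'   document outside it raises a `chv_reference_error`.
#' @param decimals,round_mode Reporting convention for percentages.
#' @param lexicons Category lexicons for [categorize_missing()].
#' @return An object of class `chv_evaluation`: `terms` (per-term records),
#'   `overall` (one-row data.frame), `by_group`, `group_average`,
#'   `missing_by_category`, `round_mode`.
#' @details An annotation set with no countable terms raises a
#'   `chv_undefined_statistic_error`. The partition invariants
#'   (covered + missing == total; similar + different == covered) are
#'   asserted on every run.
#' @export
evaluate_corpus <- function(annotations, mappings, index,
                            policy = counting_policy(), groups = NULL,
                            doc_ids = NULL, decimals = 2L,
                            round_mode = "nearest",
                            lexicons = default_missing_lexicons()) {
  stopifnot(is.data.frame(annotations),
            all(c("doc_id", "surface") %in% names(annotations)),
            inherits(index, "chv_index"))
  if (!inherits(policy, "chv_counting_policy")) {
    policy <- do.call(counting_policy, as.list(policy))
  }
  if (!is.null(doc_ids)) {
    bad <- setdiff(unique(annotations$doc_id), doc_ids)
    if (length(bad)) {
      chv_error(sprintf("annotations reference unknown document(s): %s",
                        paste(bad, collapse = ", ")), "chv_reference_error")
    }
  }
  ann <- annotations
  n <- nrow(ann)
  if (!("include_flag" %in% names(ann))) ann$include_flag <- rep(TRUE, n)
  ann$include_flag[is.na(ann$include_flag)] <- TRUE
  if (!("category_override" %in% names(ann))) {
    ann$category_override <- rep(NA_character_, n)
  }
  if (!("group" %in% names(ann))) {
    ann$group <- if (!is.null(groups)) {
      unname(groups[ann$doc_id])
    } else {
      rep(NA_character_, n)
    }
  }
  ann$group[is.na(ann$group) | !nzchar(ann$group)] <- "all"
  ann$norm <- normalize_term(ann$surface)

  excluded <- (!ann$include_flag) | (ann$norm %in% policy$exclusion_list)
  dup <- rep(FALSE, n)
  if (n) dup <- duplicated(paste(ann$doc_id, ann$norm, sep = "\r")) & !excluded
  counted <- !excluded & !dup

  # best mapping per (doc, normalized surface): prefer one whose concept has
  # a preferred term, then higher score, then smaller cui
  lookup <- new.env(parent = emptyenv())
  if (nrow(mappings)) {
    mp <- mappings
    mp$norm <- normalize_term(mp$surface)
    mp$pref <- preferred_term(index, mp$cui)
    ord <- order(mp$doc_id, mp$norm, is.na(mp$pref), -mp$score, mp$cui)
    mp <- mp[ord, , drop = FALSE]
    key <- paste(mp$doc_id, mp$norm, sep = "\r")
    first <- !duplicated(key)
    for (i in which(first)) {
      assign(key[i], list(cui = mp$cui[i], pref = mp$pref[i]), envir = lookup)
    }
  }

  status <- ifelse(excluded, "excluded", NA_character_)
  cui <- rep(NA_character_, n)
  pref <- rep(NA_character_, n)
  similarity <- rep("not_applicable", n)
  category <- rep(NA_character_, n)
  for (i in which(counted)) {
    hit <- mget(paste(ann$doc_id[i], ann$norm[i], sep = "\r"),
                envir = lookup, ifnotfound = list(NULL))[[1L]]
    if (!is.null(hit) && !is.na(hit$pref)) {
      status[i] <- "covered"
      cui[i] <- hit$cui
      pref[i] <- hit$pref
      similarity[i] <- classify_similarity(ann$surface[i], hit$pref)
    } else {
      status[i] <- "missing"
      category[i] <- categorize_missing(ann$surface[i], lexicons,
                                        override = ann$category_override[i])
    }
  }

  terms <- data.frame(doc_id = ann$doc_id, surface = ann$surface,
                      cui = cui, preferred = pref, status = status,
                      similarity = similarity, category = category,
                      group = ann$group, counted = counted,
                      stringsAsFactors = FALSE)
  terms <- terms[!dup, , drop = FALSE]
  rownames(terms) <- NULL

  cnt <- terms[terms$counted, , drop = FALSE]
  if (!nrow(cnt)) {
    chv_error("no countable terms in the annotation set",
              "chv_undefined_statistic_error")
  }

  summarize <- function(sub, label) {
    covered <- sum(sub$status == "covered")
    missing <- sum(sub$status == "missing")
    similar <- sum(sub$similarity == "similar")
    different <- sum(sub$similarity == "different")
    total <- covered + missing
    stopifnot(similar + different == covered)
    data.frame(group = label, n_reports = length(unique(sub$doc_id)),
               similar = similar, different = different, missing = missing,
               covered = covered, total = total,
               coverage_pct = if (total > 0) {
                 content_coverage(covered, total, decimals, round_mode)
               } else {
                 NA_real_
               },
               similarity_pct = if (covered > 0) {
                 lexical_similarity(similar, covered, decimals, round_mode)
               } else {
                 NA_real_
               },
               stringsAsFactors = FALSE)
  }

  overall <- summarize(cnt, "overall")
  stopifnot(sum(terms$status == "excluded") + overall$covered +
              overall$missing == nrow(terms))

  grp_labels <- unique(cnt$group)
  by_group <- do.call(rbind, lapply(grp_labels, function(g) {
    summarize(cnt[cnt$group == g, , drop = FALSE], g)
  }))
  group_average <- list(
    coverage_pct = round_pct(mean(by_group$coverage_pct, na.rm = TRUE),
                             decimals, round_mode),
    similarity_pct = round_pct(mean(by_group$similarity_pct, na.rm = TRUE),
                               decimals, round_mode))

  miss <- cnt[cnt$status == "missing", , drop = FALSE]
  cat_levels <- c(.missing_categories, "uncategorized")
  mb <- table(factor(miss$category, levels = cat_levels))
  missing_by_category <- data.frame(
    category = cat_levels, count = as.integer(mb),
    share_pct = if (nrow(miss)) {
      round_pct(as.integer(mb) * 100 / nrow(miss), 0L, "nearest")
    } else {
      rep(NA_real_, length(cat_levels))
    },
    stringsAsFactors = FALSE)
  stopifnot(sum(missing_by_category$count) == overall$missing)

  structure(list(terms = terms, overall = overall, by_group = by_group,
                 group_average = group_average,
                 missing_by_category = missing_by_category,
                 round_mode = round_mode),
            class = "chv_evaluation")
}

#' @export
print.chv_evaluation <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<chv_evaluation> %d terms in %d report(s): coverage ",
                     "%s%%, lexical similarity %s%%\n"),
              o$total, o$n_reports, format(o$coverage_pct),
              format(o$similarity_pct)))
  print(x$by_group, row.names = FALSE)
  invisible(x)
}
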