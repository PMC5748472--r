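# Synthetic vocabulary, report, MMI and annotation generator with known
# ground truth, so every pipeline stage is testable without a licensed
# vocabulary release or an external concept mapper.

#' Generator configuration
#'
#' Defaults emulate the statistical structure of a small multi-modality
#' radiology corpus: 31 reports across five imaging modalities, 15--25
#' evaluated terms per report, about 90% of term instances covered by the
#' vocabulary and about 70% of covered concepts carrying a same-stem
#' preferred term, with missing terms spread over the four coverage-gap
#' categories in proportions 51:28:12:6.
#'
#' @param n_concepts Number of vocabulary concepts.
#' @param n_reports Number of reports.
#' @param terms_per_report Integer range (lo, hi) of evaluated terms per
#'   report; terms are sampled without replacement within a report.
#' @param p_covered Probability a report term exists in the vocabulary.
#' @param p_similar_pref Probability a covered concept's preferred term is a
#'   same-stem variant of its clinical surface.
#' @param p_dup_pref Probability a concept carries two preferred-term rows.
#' @param category_mix Probabilities over the four missing-term categories.
#' @param seed Random seed (mandatory).
#' @param groups Modality labels cycled over reports.
#' @return A list of class `chv_generator_config`.
#' @export
generator_config <- function(n_concepts = 300L, n_reports = 31L,
                             terms_per_report = c(15L, 25L),
                             p_covered = 0.9, p_similar_pref = 0.7,
                             p_dup_pref = 0.05,
                             category_mix = c(anatomy = 51,
                                              anatomical_description = 28,
                                              technique_projection = 12,
                                              physiology = 6) / 97,
                             seed,
                             groups = c("mri", "ultrasound", "ct",
                                        "nuclear_medicine", "xray")) {
  if (missing(seed) || is.null(seed)) {
    chv_error("a seed is mandatory for the generator", "chv_config_error")
  }
  probs <- c(p_covered, p_similar_pref, p_dup_pref, category_mix)
  if (any(probs < 0) || any(probs > 1) || abs(sum(category_mix) - 1) > 1e-8) {
    chv_error("probabilities must lie in [0,1] and category_mix must sum to 1",
              "chv_config_error")
  }
  if (n_concepts < 1L || n_reports < 1L ||
      n_concepts < max(terms_per_report)) {
    chv_error("need n_concepts >= upper bound of terms_per_report and positive sizes",
              "chv_config_error")
  }
  structure(list(n_concepts = as.integer(n_concepts),
                 n_reports = as.integer(n_reports),
                 terms_per_report = as.integer(terms_per_report),
                 p_covered = p_covered, p_similar_pref = p_similar_pref,
                 p_dup_pref = p_dup_pref, category_mix = category_mix,
                 seed = as.integer(seed), groups = groups),
            class = "chv_generator_config")
}

# Pseudo-medical word factory: pronounceable stem + clinical affix, globally
# unique, deliberately avoiding real drug/disease names.
.word_factory <- function() {
  onsets <- c("bar", "cor", "dal", "fen", "gor", "hul", "jas", "kel", "lem",
              "mor", "nar", "pel", "quor", "ros", "sil", "tav", "ver", "wex",
              "yol", "zem")
  mids <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ru",
            "sa", "te", "vi", "xo")
  used <- new.env(parent = emptyenv())
  make <- function(suffix = "") {
    for (attempt in 1:1000) {
      w <- paste0(sample(onsets, 1L), sample(mids, 1L),
                  if (stats::runif(1) < 0.5) sample(mids, 1L) else "",
                  suffix)
      if (!exists(w, envir = used)) {
        assign(w, TRUE, envir = used)
        return(w)
      }
    }
    chv_error("word pool exhausted", "chv_config_error")
  }
  list(make = make,
       reserve = function(w) assign(w, TRUE, envir = used),
       taken = function(w) exists(w, envir = used))
}

.clinical_suffixes <- c("osis", "itis", "oma", "opathy", "ectomy", "ogram",
                        "emia", "algia", "iasis", "plasty")

#' Generate a synthetic vocabulary in MRCONSO dialect
#'
#' Builds `n_concepts` concepts with a clinical surface and a consumer
#' preferred term. For a `p_similar_pref` fraction the preferred term is an
#' inflectional variant of the surface (identity, plural, gerund or
#' adjectival form) that the similarity classifier labels Similar by
#' construction — the generator asserts this at build time, so similarity
#' recovery downstream is exact. The remainder get a lexically unrelated
#' preferred term (single unrelated word or a two-word phrase), asserted
#' Different. A `p_dup_pref` fraction carries two preferred-term rows with
#' distinct AUIs (the smaller AUI holds the ground-truth preferred string).
#' Clinical surfaces distinct from the preferred term are emitted as synonym
#' (`SY`) rows, and occasional rows of a second source exercise source
#' filtering. Output is valid 18-field RRF.
#'
#' @param config A [generator_config()].
#' @return A list with `rrf_lines` (character vector) and `concepts`
#'   (data.frame: `cui`, `surface`, `preferred`, `similarity` gold label,
#'   `dup_pref`).
#' @export
make_vocabulary <- function(config) {
  stopifnot(inherits(config, "chv_generator_config"))
  set.seed(config$seed)
  wf <- .word_factory()
  lines <- character(0)
  aui_counter <- 0L
  next_aui <- function() {
    aui_counter <<- aui_counter + 1L
    sprintf("A%07d", aui_counter)
  }
  rrf_line <- function(cui, str, sab, tty, ispref = "Y", ts = "P") {
    paste(cui, "ENG", ts, "L0000000", "PF", "S0000000", ispref, next_aui(),
          "", "", "", sab, tty, "0000", str, "0", "N", "", sep = "|")
  }

  n <- config$n_concepts
  cui <- sprintf("C%07d", 1000000L + seq_len(n))
  surface <- character(n)
  preferred <- character(n)
  gold_sim <- character(n)
  dup_pref <- stats::runif(n) < config$p_dup_pref
  similar <- stats::runif(n) < config$p_similar_pref

  for (i in seq_len(n)) {
    w <- wf$make(sample(.clinical_suffixes, 1L))
    surface[i] <- w
    if (similar[i]) {
      variant <- switch(sample(4L, 1L),
                        w,
                        paste0(w, "s"),
                        paste0(w, "ing"),
                        paste0(w, "al"))
      if (wf$taken(variant) && variant != w) variant <- paste0(w, "s")
      wf$reserve(variant)
      preferred[i] <- variant
      gold_sim[i] <- "similar"
      stopifnot(classify_similarity(w, variant) == "similar")
    } else {
      pref <- if (stats::runif(1) < 0.5) {
        paste(wf$make(""), wf$make(sample(.clinical_suffixes, 1L)))
      } else {
        repeat {
          cand <- wf$make(sample(.clinical_suffixes, 1L))
          if (classify_similarity(w, cand) == "different") break
        }
        cand
      }
      preferred[i] <- pref
      gold_sim[i] <- "different"
      stopifnot(classify_similarity(w, pref) == "different")
    }

    lines <- c(lines, rrf_line(cui[i], preferred[i], "CHV", "PT"))
    if (dup_pref[i]) {
      alt <- paste0(preferred[i], "um")
      wf$reserve(alt)
      lines <- c(lines, rrf_line(cui[i], alt, "CHV", "PT"))
    }
    if (surface[i] != preferred[i]) {
      lines <- c(lines, rrf_line(cui[i], surface[i], "CHV", "SY",
                                 ispref = "N", ts = "S"))
    }
    if (stats::runif(1) < 0.05) {
      lines <- c(lines, rrf_line(cui[i], wf$make("ensis"), "MSH", "PT"))
    }
  }

  concepts <- data.frame(cui = cui, surface = surface, preferred = preferred,
                         similarity = gold_sim, dup_pref = dup_pref,
                         stringsAsFactors = FALSE)
  list(rrf_lines = lines, concepts = concepts)
}

.sentence_templates_2 <- c(
  "There is a %s within the %s.",
  "The %s appears prominent adjacent to the %s.",
  "No evidence of %s involving the %s.",
  "Mild %s is seen along the %s.")
.sentence_templates_1 <- c(
  "The %s is unremarkable.",
  "Interval stability of the %s.")

# fill a template, returning the sentence and 0-based spans of the terms
.fill_template <- function(tmpl, terms) {
  parts <- strsplit(tmpl, "%s", fixed = TRUE)[[1L]]
  if (!grepl("%s$", tmpl)) {
    fixed <- parts
  } else {
    fixed <- c(parts, "")
  }
  out <- ""
  starts <- integer(length(terms))
  for (i in seq_along(terms)) {
    out <- paste0(out, fixed[i])
    starts[i] <- nchar(out)
    out <- paste0(out, terms[i])
  }
  out <- paste0(out, paste(fixed[-seq_along(terms)], collapse = ""))
  list(sentence = out, starts = starts)
}

#' Generate synthetic reports, annotations and ground truth
#'
#' Fills sentence templates with sampled terms: covered instances use the
#' clinical surface of a vocabulary concept, missing instances draw from
#' category-tagged out-of-vocabulary pools. Gold spans, statuses, similarity
#' labels, categories and group labels are recorded per instance, together
#' with an annotation table in the layout [evaluate_corpus()] consumes and
#' the per-category OOV lexicons (exact word lists) under which
#' [categorize_missing()] recovers every gold category.
#'
#' @param config A [generator_config()].
#' @param vocab Result of [make_vocabulary()] for the same config.
#' @return A list with `reports` (named character vector, doc_id to text),
#'   `annotations` (data.frame `doc_id`, `surface`, `include_flag`,
#'   `category_override`, `group`), `instances` (gold truth per instance:
#'   spans, status, cui, similarity, category, group) and `lexicons`.
#' @export
make_reports <- function(config, vocab) {
  stopifnot(inherits(config, "chv_generator_config"))
  set.seed(config$seed + 1L)
  concepts <- vocab$concepts

  # OOV pools: unique single-token words disjoint from the vocabulary
  wf <- .word_factory()
  for (w in c(concepts$surface,
              unlist(strsplit(concepts$preferred, " ", fixed = TRUE)))) {
    wf$reserve(w)
  }
  pool_size <- max(40L, max(config$terms_per_report))
  oov_pools <- lapply(stats::setNames(nm = names(config$category_mix)),
                      function(cat) {
                        vapply(seq_len(pool_size), function(i) wf$make("yx"),
                               character(1))
                      })

  reports <- character(0)
  ann <- list()
  inst <- list()
  lo <- config$terms_per_report[1L]
  hi <- config$terms_per_report[2L]

  for (r in seq_len(config$n_reports)) {
    doc_id <- sprintf("report_%03d", r)
    group <- config$groups[(r - 1L) %% length(config$groups) + 1L]
    n_terms <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    covered <- stats::runif(n_terms) < config$p_covered
    n_cov <- sum(covered)
    cov_idx <- sample(nrow(concepts), n_cov)
    cats <- sample(names(config$category_mix), n_terms - n_cov,
                   replace = TRUE, prob = config$category_mix)
    miss_words <- character(n_terms - n_cov)
    for (cat in unique(cats)) {
      sel <- which(cats == cat)
      miss_words[sel] <- sample(oov_pools[[cat]], length(sel))
    }

    surfaces <- character(n_terms)
    surfaces[covered] <- concepts$surface[cov_idx]
    surfaces[!covered] <- miss_words

    text <- ""
    k <- 1L
    spans <- matrix(0L, nrow = n_terms, ncol = 2L)
    while (k <= n_terms) {
      take <- if (n_terms - k >= 1L) 2L else 1L
      tmpl <- if (take == 2L) {
        sample(.sentence_templates_2, 1L)
      } else {
        sample(.sentence_templates_1, 1L)
      }
      terms_k <- surfaces[k:(k + take - 1L)]
      filled <- .fill_template(tmpl, terms_k)
      offset <- nchar(text) + if (nzchar(text)) 1L else 0L
      sep <- if (nzchar(text)) " " else ""
      text <- paste0(text, sep, filled$sentence)
      for (t in seq_len(take)) {
        spans[k + t - 1L, ] <- c(offset + filled$starts[t],
                                 offset + filled$starts[t] +
                                   nchar(terms_k[t]))
      }
      k <- k + take
    }

    reports[doc_id] <- text
    cov_pos <- which(covered)
    gold_cui <- rep(NA_character_, n_terms)
    gold_sim <- rep("not_applicable", n_terms)
    gold_cat <- rep(NA_character_, n_terms)
    gold_cui[cov_pos] <- concepts$cui[cov_idx]
    gold_sim[cov_pos] <- concepts$similarity[cov_idx]
    gold_cat[!covered] <- cats
    ann[[r]] <- data.frame(doc_id = doc_id, surface = surfaces,
                           include_flag = TRUE,
                           category_override = NA_character_,
                           group = group, stringsAsFactors = FALSE)
    inst[[r]] <- data.frame(doc_id = doc_id, start = spans[, 1L],
                            end = spans[, 2L], surface = surfaces,
                            cui = gold_cui,
                            status = ifelse(covered, "covered", "missing"),
                            similarity = gold_sim, category = gold_cat,
                            group = group, stringsAsFactors = FALSE)
  }

  list(reports = reports,
       annotations = do.call(rbind, ann),
       instances = do.call(rbind, inst),
       lexicons = oov_pools)
}

#' Generate fielded MMI lines for gold covered instances
#'
#' One MMI line per covered gold instance, carrying the gold CUI, a score
#' drawn uniformly from `score_range`, the surface as trigger text, and
#' positional info matching the gold span under `offset_base`.
#'
#' @param reports Named character vector from [make_reports()].
#' @param truth The `instances` data.frame from [make_reports()], joined
#'   with concept preferred names via `concepts` when given.
#' @param concepts Optional concepts data.frame (for the UMLS-name field).
#' @param score_range Integer interval, default `c(500, 1000)`.
#' @param seed Random seed for the score draw.
#' @param offset_base 0 or 1; added to the 0-based gold starts.
#' @return A data.frame with columns `doc_id`, `line`.
#' @export
make_mmi <- function(reports, truth, concepts = NULL,
                     score_range = c(500L, 1000L), seed = 1L,
                     offset_base = 0L) {
  set.seed(seed)
  cov <- truth[truth$status == "covered", , drop = FALSE]
  if (!nrow(cov)) {
    return(data.frame(doc_id = character(0), line = character(0),
                      stringsAsFactors = FALSE))
  }
  name_of <- if (!is.null(concepts)) {
    stats::setNames(concepts$preferred, concepts$cui)
  } else {
    NULL
  }
  scores <- score_range[1L] +
    sample.int(score_range[2L] - score_range[1L] + 1L, nrow(cov),
               replace = TRUE) - 1L
  lines <- vapply(seq_len(nrow(cov)), function(i) {
    nm <- if (!is.null(name_of)) unname(name_of[cov$cui[i]]) else cov$surface[i]
    sprintf('%s|MMI|%d|%s|%s|[fndg]|["%s"-tx-1-"%s"-noun-0]|TX|%d/%d|',
            cov$doc_id[i], scores[i], nm, cov$cui[i], cov$surface[i],
            cov$surface[i], cov$start[i] + offset_base,
            cov$end[i] - cov$start[i])
  }, character(1))
  data.frame(doc_id = cov$doc_id, line = lines, stringsAsFactors = FALSE)
}

#' Generate a full synthetic corpus, optionally writing it to disk
#'
#' Convenience wrapper chaining [make_vocabulary()], [make_reports()] and
#' [make_mmi()]. When `dir` is given, writes `vocab.rrf`, `reports/*.txt`,
#' `mmi/*.mmi`, `annotations.tsv`, `truth_concepts.tsv` and
#' `truth_instances.tsv` (all plain text; the seed is recorded in a header
#' line of the vocabulary file).
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory.
#' @param score_range,offset_base Passed to [make_mmi()].
#' @return A list with `vocab`, `reports`, `annotations`, `instances`,
#'   `lexicons`, `mmi`, invisibly when writing.
#' @export
synth_corpus <- function(config, dir = NULL, score_range = c(500L, 1000L),
                         offset_base = 0L) {
  vocab <- make_vocabulary(config)
  rep <- make_reports(config, vocab)
  mmi <- make_mmi(rep$reports, rep$instances, vocab$concepts,
                  score_range = score_range, seed = config$seed + 2L,
                  offset_base = offset_base)
  out <- list(vocab = vocab, reports = rep$reports,
              annotations = rep$annotations, instances = rep$instances,
              lexicons = rep$lexicons, mmi = mmi)
  if (is.null(dir)) return(out)

  dir.create(file.path(dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "mmi"), recursive = TRUE, showWarnings = FALSE)
  writeLines(vocab$rrf_lines, file.path(dir, "vocab.rrf"), useBytes = TRUE)
  writeLines(sprintf("# synthetic corpus, seed=%d", config$seed),
             file.path(dir, "SEED.txt"))
  for (id in names(rep$reports)) {
    writeLines(rep$reports[[id]], file.path(dir, "reports",
                                            paste0(id, ".txt")),
               useBytes = TRUE)
    sel <- mmi$line[mmi$doc_id == id]
    writeLines(sel, file.path(dir, "mmi", paste0(id, ".mmi")),
               useBytes = TRUE)
  }
  utils::write.table(rep$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(vocab$concepts, file.path(dir, "truth_concepts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(rep$instances, file.path(dir, "truth_instances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(out)
}
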