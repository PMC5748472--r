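# End-to-end orchestration: build-index -> map -> simplify -> evaluate,
# driven by a configuration object or YAML file.

#' Pipeline configuration
#'
#' Collects paths and parameters for [run_pipeline()]. Defaults encode the
#' reference setup: source label `"CHV"`, minimum mapping score 500 of 1000,
#' no semantic-type restriction (all semantic types included), bracket
#' marking on.
#'
#' @param vocabulary Path to the MRCONSO-dialect vocabulary file.
#' @param reports Directory of `*.txt` report files, or a character vector
#'   of file paths. Document ids are the file names without extension.
#' @param out_dir Output directory.
#' @param mapper `"builtin"` or `"mmi"`.
#' @param mmi_dir Directory of `<doc_id>.mmi` files (required for the mmi
#'   mapper).
#' @param annotations Optional path to a tab-delimited annotation table
#'   (`doc_id`, `surface`, `include_flag`, `category_override`, `group`).
#' @param min_score Minimum evaluation score kept (0--1000).
#' @param source_label Vocabulary source abbreviation.
#' @param sem_types Optional character vector restricting semantic types;
#'   `NULL` includes all.
#' @param offset_base MMI positional-info offset base, 0 or 1.
#' @param abbreviations Optional path to a two-column abbreviation file
#'   (short form, expansion), applied before the built-in mapper.
#' @param options A [replacement_options()] list.
#' @param round_mode `"nearest"` or `"floor"`.
#' @param exclusion_list Normalized surfaces never counted in evaluation.
#' @return A list of class `chv_pipeline_config`.
#' @export
pipeline_config <- function(vocabulary, reports, out_dir,
                            mapper = c("builtin", "mmi"), mmi_dir = NULL,
                            annotations = NULL, min_score = 500L,
                            source_label = "CHV", sem_types = NULL,
                            offset_base = 0L,
                            abbreviations = NULL,
                            options = replacement_options(),
                            round_mode = "nearest",
                            exclusion_list = character(0)) {
  mapper <- match.arg(mapper)
  if (min_score < 0L || min_score > 1000L) {
    chv_error("min_score must lie in [0, 1000]", "chv_config_error")
  }
  structure(list(vocabulary = vocabulary, reports = reports,
                 out_dir = out_dir, mapper = mapper, mmi_dir = mmi_dir,
                 annotations = annotations, min_score = as.integer(min_score),
                 source_label = source_label, sem_types = sem_types,
                 offset_base = as.integer(offset_base),
                 abbreviations = abbreviations, options = options,
                 round_mode = round_mode, exclusion_list = exclusion_list),
            class = "chv_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; the
#' `options` key is a mapping with the [replacement_options()] flag names.
#'
#' @param path YAML file path.
#' @return A `chv_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    chv_error(sprintf("config file '%s' does not exist", path),
              "chv_config_error")
  }
  y <- yaml::read_yaml(path)
  opts <- do.call(replacement_options,
                  if (is.null(y$options)) list() else y$options)
  y$options <- NULL
  do.call(pipeline_config, c(y, list(options = opts)))
}

.report_files <- function(reports) {
  files <- if (length(reports) == 1L && dir.exists(reports)) {
    list.files(reports, pattern = "\\.txt$", full.names = TRUE)
  } else {
    reports
  }
  sort(files)
}

#' Run the full simplification pipeline
#'
#' Stages: parse the vocabulary and build the preferred-term index; map each
#' report (fielded MMI files filtered by score and semantic type, or the
#' built-in longest-match mapper); resolve overlaps; apply preferred-term
#' replacements; and, when an annotation table is supplied, evaluate
#' coverage and lexical similarity. All outputs are written under
#' `config$out_dir`: the persisted index, `mappings.tsv`, simplified report
#' texts, `replacement_log.tsv`, and (with annotations) `term_records.tsv`,
#' `summary.tsv` and `missing_categories.tsv`. Every stage logs its counts
#' via `message()`. Outputs are pure functions of inputs plus configuration;
#' running the same configuration twice produces identical files.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the `index`, `mappings`, `simplified`
#'   documents and the `evaluation` (or `NULL`).
#' @details Missing input paths raise a `chv_config_error` before any stage
#'   runs or any output is written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "chv_pipeline_config"))

  report_files <- .report_files(config$reports)
  inputs <- c(config$vocabulary, report_files,
              config$annotations, config$abbreviations)
  missing_in <- inputs[!file.exists(inputs)]
  if (!length(report_files)) missing_in <- c(missing_in, "reports")
  if (length(missing_in)) {
    chv_error(sprintf("missing input(s): %s",
                      paste(missing_in, collapse = ", ")),
              "chv_config_error")
  }
  doc_ids <- sub("\\.txt$", "", basename(report_files))
  if (config$mapper == "mmi") {
    mmi_files <- file.path(config$mmi_dir, paste0(doc_ids, ".mmi"))
    if (is.null(config$mmi_dir) || !all(file.exists(mmi_files))) {
      chv_error("mmi mapper selected but mmi files are missing",
                "chv_config_error")
    }
  }

  # stage 1: vocabulary index
  rows <- parse_mrconso(config$vocabulary)
  index <- build_index(rows, config$source_label)
  message(sprintf("vocabulary: %d rows parsed, %d concepts indexed (%d ambiguous, %d synonym-only)",
                  nrow(rows), length(index$preferred),
                  length(index$ambiguous_cuis), length(index$sy_only_cuis)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_index(index, file.path(config$out_dir, "index"))

  abbrevs <- if (!is.null(config$abbreviations)) {
    ab <- utils::read.delim(config$abbreviations, header = FALSE,
                            stringsAsFactors = FALSE)
    stats::setNames(as.character(ab[[2L]]), as.character(ab[[1L]]))
  } else {
    character(0)
  }

  # stage 2: mapping
  texts <- stats::setNames(vapply(report_files, function(f) {
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1), USE.NAMES = FALSE), doc_ids)

  all_maps <- list()
  for (id in doc_ids) {
    if (config$mapper == "mmi") {
      recs <- parse_mmi(file.path(config$mmi_dir, paste0(id, ".mmi")))
      recs$doc_id <- rep(id, nrow(recs))
      recs <- filter_records(recs, config$min_score, config$sem_types)
      maps <- mmi_to_mappings(recs, texts[[id]], config$offset_base)
    } else {
      scan_text <- texts[[id]]
      exp <- NULL
      if (length(abbrevs)) {
        exp <- expand_abbreviations(scan_text, abbrevs)
        scan_text <- exp$text
      }
      maps <- builtin_map(scan_text, index, doc_id = id)
      if (!is.null(exp) && nrow(maps)) {
        for (j in seq_len(nrow(maps))) {
          sp <- original_span(exp, maps$start[j], maps$end[j])
          maps$start[j] <- sp[1L]
          maps$end[j] <- sp[2L]
          maps$surface[j] <- substr(texts[[id]], sp[1L] + 1L, sp[2L])
        }
      }
    }
    all_maps[[id]] <- resolve_overlaps(maps)
  }
  mappings <- do.call(rbind, c(all_maps, list(make.row.names = FALSE)))
  message(sprintf("mapping: %d concept hits across %d reports",
                  nrow(mappings), length(doc_ids)))
  utils::write.table(mappings, file.path(config$out_dir, "mappings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: simplification
  dir.create(file.path(config$out_dir, "simplified"), showWarnings = FALSE)
  simplified <- list()
  logs <- list()
  for (id in doc_ids) {
    sd <- apply_replacements(texts[[id]],
                             mappings[mappings$doc_id == id, , drop = FALSE],
                             index, config$options, doc_id = id)
    simplified[[id]] <- sd
    writeLines(sd$simplified_text,
               file.path(config$out_dir, "simplified", paste0(id, ".txt")),
               useBytes = TRUE)
    if (nrow(sd$replacements)) {
      logs[[id]] <- cbind(doc_id = id, sd$replacements)
    }
  }
  rlog <- if (length(logs)) {
    do.call(rbind, c(logs, list(make.row.names = FALSE)))
  } else {
    data.frame(doc_id = character(0))
  }
  message(sprintf("simplification: %d replacements written",
                  sum(rlog$action == "replaced")))
  utils::write.table(rlog, file.path(config$out_dir, "replacement_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: evaluation
  evaluation <- NULL
  if (!is.null(config$annotations)) {
    ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
    evaluation <- evaluate_corpus(
      ann, mappings, index,
      policy = counting_policy(exclusion_list = config$exclusion_list),
      doc_ids = doc_ids, round_mode = config$round_mode)
    message(sprintf("evaluation: %d terms, coverage %s%%, similarity %s%%",
                    evaluation$overall$total,
                    format(evaluation$overall$coverage_pct),
                    format(evaluation$overall$similarity_pct)))
    utils::write.table(evaluation$terms,
                       file.path(config$out_dir, "term_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary_tbl <- rbind(evaluation$by_group, evaluation$overall)
    utils::write.table(summary_tbl,
                       file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(evaluation$missing_by_category,
                       file.path(config$out_dir, "missing_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(index = index, mappings = mappings,
                 simplified = simplified, evaluation = evaluation))
}
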