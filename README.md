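# chvsimplify

Lexical simplification of radiology reports with a consumer health
vocabulary (CHV), plus the statistics to judge whether the vocabulary is up
to the job.

Radiology reports published to patient portals are written in clinical
language. A CHV — an open terminology of lay synonyms distributed as a
source inside the UMLS Metathesaurus — assigns each unified concept (CUI) a
consumer-preferred term. This package implements the full pipeline around
such a vocabulary, for informaticians studying consumer-facing clinical
text:

* **Vocabulary**: parse MRCONSO-dialect RRF files (pipe-delimited, 18
  fields) and build a CUI → preferred-term index with a surface-form lookup
  (`parse_mrconso()`, `build_index()`). Duplicate preferred terms per CUI
  are resolved deterministically (smallest AUI) and flagged.
* **Mapping**: ingest MetaMap fielded MMI output (`parse_mmi()`,
  `filter_records()`, `mmi_to_mappings()`) with the score threshold
  (default ≥ 500 of 1000) and optional semantic-type filter, or map with a
  built-in dictionary longest-match mapper (`builtin_map()`); predefine
  abbreviations with `expand_abbreviations()`.
* **Simplification**: replace mapped spans with bracket-marked preferred
  terms, with overlap resolution, a/an agreement, case transfer and an
  optional same-stem skip guard (`apply_replacements()`); every run is
  reversible byte-for-byte (`revert_simplification()`).
* **Evaluation**: per-report term counting with exclusion and
  deduplication rules, then

  ```
  content coverage   = covered terms x 100 / total terms
  lexical similarity = similar terms x 100 / covered terms
  ```

  where *similar* means a perfect one-to-one matching between the token
  multisets of term and preferred term under a same-stem variant test
  (Porter stem equality, or a common prefix of at least
  `max(4, ceil(0.6 x len(shorter)))` characters). Uncovered terms are
  sorted into four gap categories (anatomy, anatomical description,
  technique/projection, physiology). See `evaluate_corpus()`,
  `classify_similarity()`, `content_coverage()`, `lexical_similarity()`.
* **Synthetic data**: a seeded generator (`synth_corpus()`) that emits a
  miniature vocabulary, reports, MMI files and annotations with known
  ground truth, so the whole pipeline is testable without licensed UMLS
  data or MetaMap.
* **Orchestration**: `run_pipeline()` (or the thin CLI at
  `inst/cli/chvsimplify.R`) chains build-index → map → simplify → evaluate
  from a config object or YAML file.

## Worked example

```r
library(chvsimplify)

vocab_lines <- c(
  "C0027540|ENG|P|L0|PF|S0|Y|A0000001||||CHV|PT|0000|tissue death|0|N||",
  "C0027540|ENG|S|L0|PF|S0|N|A0000002||||CHV|SY|0000|necrosis|0|N||",
  "C0013687|ENG|P|L0|PF|S0|Y|A0000003||||CHV|PT|0000|effusion|0|N||",
  "C0013687|ENG|S|L0|PF|S0|N|A0000004||||CHV|SY|0000|free fluid|0|N||",
  "C0205400|ENG|P|L0|PF|S0|Y|A0000005||||CHV|PT|0000|thickened|0|N||",
  "C0205400|ENG|S|L0|PF|S0|N|A0000006||||CHV|SY|0000|thickening|0|N||")
idx <- build_index(parse_mrconso(vocab_lines))

report <- "There is a free fluid collection. Mural thickening with necrosis is noted."
maps <- resolve_overlaps(builtin_map(report, idx, doc_id = "r1"))
sd <- apply_replacements(report, maps, idx, doc_id = "r1")
sd$simplified_text
#> "There is an [effusion] collection. Mural [thickened] with [tissue death] is noted."

ann <- data.frame(doc_id = "r1",
                  surface = c("free fluid", "thickening", "necrosis",
                              "midthoracic"))
evaluate_corpus(ann, maps, idx)
#> <chv_evaluation> 4 terms in 1 report(s): coverage 75%, lexical similarity 33.33%
```

Reading the output: three of the four annotated terms map to a concept
with a preferred term (coverage 75%). Of those, only *thickening* →
*thickened* shares a stem (similarity 33.33%); *free fluid* → *effusion*
and *necrosis* → *tissue death* are lexically different replacements, and
*midthoracic* is missing from the vocabulary and lands in the anatomy gap
category. Note the article repair: "a free fluid" became "an [effusion]".

## Command line

```sh
Rscript inst/cli/chvsimplify.R synth --seed 42 --out corpus
Rscript inst/cli/chvsimplify.R evaluate --vocab corpus/vocab.rrf \
    --reports corpus/reports --annotations corpus/annotations.tsv --out out
```

Subcommands: `build-index`, `map`, `simplify`, `evaluate`, `synth`, `run`
(end-to-end from a YAML config). See the header of the script for all
flags.
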