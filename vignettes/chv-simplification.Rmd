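---
title: "Simplifying radiology reports with a consumer health vocabulary: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplifying radiology reports with a consumer health vocabulary: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chvsimplify)
```

## The problem and the procedure

Radiology reports delivered through patient portals are written for
clinicians: they are dense with anatomical, pathological and
technique-specific terms that lay readers cannot parse. Lexical
simplification replaces difficult terms with simpler synonyms without
restructuring sentences. A consumer health vocabulary (CHV) — a terminology
of lay-friendly synonyms distributed as a source inside the UMLS
Metathesaurus — supplies, for each unified concept (CUI), a
consumer-preferred term that can stand in for the clinical one.

The pipeline in this package has two stages.

**Translation.** Terms in report text are linked to concepts, either by
ingesting MetaMap fielded MMI output (one concept hit per pipe-delimited
line, with a 0–1000 evaluation score, trigger terms and character
positions) or by the package's built-in dictionary longest-match mapper.
Hits below a score threshold are dropped; the default threshold of 500 out
of 1000 is deliberately low so the net is cast wide, and by default no
semantic-type restriction is applied — all semantic types are included.
Each mapped span is then replaced by the consumer-preferred term of its
concept, looked up in an index built from the MRCONSO concept-names table,
and marked with square brackets, e.g. `[tissue death]`, so replacements
remain recognizable downstream.

**Evaluation.** Annotated terms of interest are counted per report (each
term once per report, except that a full form and its abbreviation count as
two distinct terms; simple-English words on an exclusion list are not
counted), and two statistics are computed:

* content coverage = covered terms × 100 / total terms,
* lexical similarity = similar terms × 100 / covered terms,

where a covered term is one that maps to a concept with a preferred term,
and *similar* / *different* is decided by the stem-based classifier below.
Terms the vocabulary does not cover are sorted into four categories:
human anatomical structures and regions, anatomical descriptions and
pathological variations, radiology techniques and projections, and
physiology-related terms.

## The similarity classifier

A term and its preferred term are tokenized, lowercased, and stripped of a
minimal stopword list (`a an the of and or to in`). The pair is **similar**
when a perfect one-to-one matching exists between the two token multisets
under the single-token variant test; otherwise **different**. Requiring a
bijection means equal token counts: a preferred term that *adds* a content
word ("heart ventricle" for "ventricle") is different, while a paraphrase
of the same words ("wall of abdomen" for "abdominal wall") is similar.

The single-token variant test accepts two words when

* their Porter stems are equal (the original 1980 algorithm is implemented
  in `stem_token()`; e.g. *thickening* and *thickened* both stem to
  *thicken*), **or**
* their longest common prefix reaches `max(4, ceiling(0.6 × nchar(shorter)))`
  characters.

The prefix fallback is needed because derivational morphology defeats pure
stemming: *abdominal* stems to *abdomin* but *abdomen* to itself, yet the
pair must count as same-stem variants. The threshold is the smallest rule
that admits *abdominal*/*abdomen* (common prefix "abdom", 5 ≥ max(4,
⌈0.6·7⌉) = 5) while rejecting short accidental prefixes such as
*posterior*/*postcontrast* ("post", 4 < 6). It is a tunable convention, not
a linguistic law; q/c alternations like *opaque*/*opacity* (common prefix
"opa") fall below it and are classified different. The bipartite matching
is computed with an augmenting-path algorithm; tests verify it against
brute-force enumeration of all token bijections for phrases up to four
tokens.

## Building the preferred-term index

The index keeps, per CUI, the `STR` of the source's `TTY == "PT"` rows.
Consumer-vocabulary releases occasionally carry **two** preferred-term rows
for one CUI (e.g. both "change" and "modified"); the vocabulary's public
browser shows a single preferred term, but no rule recoverable from MRCONSO
reproduces that choice. The package therefore resolves deterministically —
the row with the lexicographically smallest AUI wins — and flags the CUI in
`ambiguous_cuis` so the ambiguity is surfaced rather than hidden. The
tie-break depends only on row content, so permuting the input never changes
the index. If a source has no `PT` rows at all, `TS == "P"` with
`ISPREF == "Y"` marks the preferred term instead, since term-type
conventions vary across releases. Normalization (lowercasing, whitespace
collapsing, stripping enclosing punctuation) is applied to lookup surfaces
only; replacement always emits the vocabulary's original casing.

## Replacement mechanics

Overlapping concept hits are reduced to a disjoint set by a fixed priority
(longer span, then smaller start, then higher score, then smaller CUI) —
longest-span-first keeps multiword matches like "renal cortex" intact
instead of replacing "cortex" inside them. Replacement then walks the text
left to right, recording for every mapping the input span, the output span
and the action taken (`replaced`, `skipped_similar`, `skipped_no_pt`). The
log is complete enough that `revert_simplification()` reconstructs the
original byte-for-byte; this reversibility is property-tested on a
thousand generated documents.

Two small grammatical repairs are applied. A leading capital on the
original surface is transferred to the replacement, except for fully
uppercase acronyms (their replacement is an expansion, which should stay
lowercase). The articles *a*/*an* are re-agreed with the first letter of
the replacement word — a letter-level rule, so "an hour"-type phonetics are
a documented limitation. Part-of-speech repair (the *opaque* → *opacity*
class of errors) is deliberately not attempted: the replacement is emitted
as-is, and with the stem guard on the near-identity is recorded instead of
replaced.

## The synthetic corpus generator

Licensed vocabulary releases and the external mapper cannot ship with the
package, so every stage is exercised on generated data with known ground
truth. The generator's defaults are the study conditions the package
targets: 31 reports cycled over five modality labels, 15–25 evaluated
terms per report, `p_covered = 0.9`, `p_similar_pref = 0.7`,
`p_dup_pref = 0.05`, and missing terms spread over the four gap categories
in proportions 51:28:12:6. Surfaces are pseudo-medical words built from
stem and affix pools — deliberately not real clinical terms, so fixtures
are unambiguous and license-free.

Two properties are guaranteed by construction and asserted at build time:
a "similar" concept's preferred term is an inflectional variant the
classifier actually labels Similar, and a "different" concept's preferred
term is either an unrelated word verified Different or a two-word phrase
(different by token count). All generated strings are globally unique, and
out-of-vocabulary words carry a marker suffix no vocabulary word uses, so
a term's gold status is exactly recoverable from the pipeline — the
parameter-recovery test demands zero label discrepancies, not approximate
agreement, and the pooled coverage/similarity then land within binomial
noise of the generating probabilities (3 and 4 percentage points at the
test's corpus size of 100 reports, roughly two thousand term instances).

What the generator does *not* emulate: real radiology syntax, misspellings
(MetaMap simply fails on them), sense ambiguity ("ultrasound" mapping to a
therapy concept), abbreviation ambiguity, or annotator judgment in term
selection. Passing tests therefore demonstrate the mechanics of the
pipeline and statistics, not corpus-level performance on real reports —
which is why evaluation takes a human annotation table as ground truth
rather than trying to automate term selection.

## Numerical conventions

* **Offsets.** All character spans are 0-based and half-open. MMI
  positional conventions vary across MetaMap releases, so the offset base
  is an explicit `{0,1}` switch rather than a guess.
* **Scores.** Decimal MMI scores are rounded to the nearest integer on the
  0–1000 scale; filtering keeps a score exactly equal to the threshold.
* **Rounding.** Published percentage tables mix conventions, so
  `round_pct()` exposes both: half-up rounding at 2 decimals (the
  per-modality convention) and truncation at 1 decimal (the covered-terms
  table: 505×100/695 = 72.66… prints as 72.6). Missing-category shares use
  nearest-integer rounding. Callers choose per statistic.
* **Degenerate inputs.** Coverage of zero evaluated terms and similarity
  of zero covered terms are undefined and raise classed errors rather than
  returning NaN; per-group summaries with no covered terms report `NA`.
* **Pooled vs macro-averaged.** Pooled percentages (sums over the corpus)
  and unweighted group averages generally differ; both are reported, and
  the summary keeps them clearly apart.

## Missing-term categorization

Categories are assigned by a keyword lexicon: an entry matches a surface's
token exactly, a prefix or suffix of the surface, or — for entries of four
or more characters — a substring inside a token, so a lexicon stem like
`thorac` captures `midthoracic`. The shipped default lexicon is a small
seed; an explicit per-term override from the annotation table always wins,
and the generator emits its own exact-word lexicons so gold categories are
recovered without heuristics. Categories are tried in a fixed order
(anatomy, anatomical description, technique/projection, physiology), so a
surface matching several lexicons resolves deterministically.

## Problem sizes

The test suite runs entirely on generated data: corpora of 10–100 reports
for unit and recovery tests, 1,000 short documents for the reversibility
property, and 100-report corpora (~2,000 term instances) in the
parameter-recovery check, chosen to put binomial confidence bounds well
inside the asserted tolerances. The whole suite completes in well under a
minute on one core.

## Known limitations

* The smallest-AUI tie-break is a reproducible stand-in, not the
  vocabulary portal's (unpublished) rule for choosing among duplicate
  preferred terms.
* The article rule is orthographic, not phonetic.
* The variant-prefix threshold misclassifies stem alternations whose
  shared prefix is short (*opaque*/*opacity*).
* The built-in mapper is exact dictionary lookup: no variant generation,
  no word-sense disambiguation, no negation handling. It exists so the
  pipeline runs and is testable without the external mapper, not as a
  re-implementation of it.
* Semantic (ontology-distance) similarity is out of scope; the evaluation
  is purely lexical.
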