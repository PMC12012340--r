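---
title: "Screening charts for hospital-acquired pulmonary embolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening charts for hospital-acquired pulmonary embolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`peaescreen` screens one hospital admission at a time for pulmonary
embolism occurring as a hospital-acquired adverse event (PEAE). This
vignette is the package's own account of the method: the procedure and its
assumptions, the parameters that matter, the synthetic data that stands in
for real charts, and the numerical conventions adopted where the design was
genuinely open.

## The screening procedure

The clinical question has two parts: was a PE diagnosed during the stay,
and if so, did it *develop* during the stay (rather than being present on
admission, community-acquired, or historical)? The pipeline encodes both
parts in a single prompt to a generation backend, because the decision is
ultimately one binary screen per admission; splitting it into two backend
calls would double cost without changing the evidence either call sees.

```{r, eval = FALSE}
library(peaescreen)
gen <- generate_corpus(generator_config(n_patients = 500,
                                        prevalence = 0.05, seed = 1))
run <- run_pipeline(run_config(method = "keyword", n_boot = 2000, seed = 1),
                    corpus = gen$corpus)
render_metric_table(run$metrics)
```

Stages, per chart:

1. **Chunking.** Every clinical note (the discharge summary excluded — it
   has its own module) is split into retrieval units. Default: paragraphs
   on blank lines, with a word-window fallback at `max_words = 128` for
   oversized paragraphs, `overlap = 0`. Paragraphs are the default because
   clinical notes are habitually paragraph-structured and a paragraph is
   the smallest unit that usually keeps an assertion and its negation or
   timing together; sentences and raw word windows are available where
   documentation style defeats that assumption. Chunk spans are 0-based
   half-open character offsets into the source note, and a chunk's text
   always equals the note substring at its span, so every retained chunk
   remains auditable back to its source.

2. **Filtering.** Keyword retrieval keeps chunks containing at least one
   term of a `keyword_spec()`. Short abbreviations (`"PE"`) match
   case-sensitively at word boundaries — "hoPEful", "peak" and "spent"
   never hit — while phrases and lowercase variants (`"pe"`, `"ctpe"`,
   `"blood clot"`, ...) match case-insensitively at word boundaries. The
   printed default list is a starting set, not a closed vocabulary.
   Semantic retrieval embeds chunks and exemplar sentences, scores each
   chunk by its **maximum** cosine similarity over the exemplars (a chunk
   need resemble only one exemplar genre; mean aggregation is available),
   and keeps the top `top_percent` (default 5%), ties broken toward the
   earlier document position, output restored to document order. The
   retained count is exactly `ceiling(top_percent/100 * n)`.

3. **Discharge extraction.** The backend is instructed to return the six
   discharge-summary sections as JSON. Parsing is total: the first balanced
   JSON block wins (instruction-tuned models commonly echo examples, so
   later blocks are distrusted), code fences and leading prose are
   tolerated, keys match case- and punctuation-insensitively, and a
   `key: value` line format is accepted as fallback. Recovering some but
   not all sections yields status `partial` rather than failure, so
   downstream prompts can use whatever was recovered.

4. **Detection.** The prompt contains, in order: the task instruction, the
   admission and discharge dates, the evidence chunks oldest-first with
   their dates, the discharge sections (when requested and not failed), and
   the output instruction. Model-family dialects (`[INST]`,
   `<|im_start|>`, role headers) are applied as a final wrap that never
   alters the payload. When evidence must be truncated to a character
   budget, the oldest lines are dropped first and the drop count is logged.
   The generated answer is classified by the first sentence — text up to
   the first `.`, `!`, `?` or newline — which is positive iff it contains
   the word "yes" at a word boundary, case-insensitively ("yesterday" is
   not an answer). Empty or failed generations classify as 0 with a flag
   rather than erroring: a screening tool must be total over a corpus.

## Evaluation conventions

* **Metrics** are percentages: PPV, sensitivity, specificity, NPV, F1. A
  zero denominator yields 0 with a `degenerate` flag rather than `NaN`.
* **Bootstrap.** Patients (the analysis unit) are resampled with
  replacement, `n_boot = 10000` by default; each metric's distribution is
  summarized by its mean and the percentile interval at `ci_level = 0.95`.
  Resamples where a metric is degenerate are skipped for that metric and
  counted. Percentile intervals were chosen over normal approximations
  because the metrics are bounded and, at realistic prevalence, strongly
  skewed. Everything is reproducible under the configured seed.
* **Surveillance.** Patients are binned by admission date at year,
  year-quarter or year-month granularity; actual and predicted incidence
  *proportions* per bin are compared by MSE, Pearson *r*, and *R*² defined
  as the squared Pearson correlation of the two series. Proportions (not
  counts) keep the scores comparable across bins of unequal size. Fewer
  than two bins, or a zero-variance actual series, flag the trend metrics
  as undefined instead of erroring. One property worth stating explicitly:
  when true prevalence is constant over time and the screen's errors are
  independent per-patient false positives, the *population* correlation
  between actual and predicted proportions is the same at every
  granularity (both signal and noise variance scale as `1/n_bin`), so
  coarser bins are not expected to raise the correlation on such corpora —
  what aggregation provably shrinks is the variance of the per-bin
  incidence error, and that is the property the test suite checks. On real
  cohorts, where incidence carries secular trends, aggregation also
  preserves trend while averaging noise, which is why yearly tracking
  looks best in practice.
* **Cohort tables** band age (<50, 50–64, 65–74, ≥75), comorbidity count
  (0, 1, ≥2) and length of stay (1–4, ≥5 days; inclusive day count), and
  test each variable against PEAE status with a chi-square test *without*
  continuity correction (Fisher's exact available); p-values below 0.001
  display as `<.001`. Quartiles everywhere use linear interpolation
  (`quantile` type 7) — IQR conventions differ enough between software
  that this is worth pinning down.
* **ICD baseline.** A chart is baseline-positive iff any coded diagnosis
  matches a configured prefix (default `I26`) and, by default, is not
  flagged present-on-admission. Real discharge-abstract rules vary by
  jurisdiction; the prefix list and POA requirement are configuration.

## The synthetic corpus: what it does and does not establish

`generate_corpus()` produces gold-labelled admissions spanning 2017–2022
with, per chart: filler notes over a 12-of-120 note-type vocabulary, a
six-section discharge summary, coded diagnoses, and demographics for cohort
tables. Positives (default prevalence 0.004, the magnitude seen in chart
review cohorts; tests mostly inflate it to 0.05 to stabilize metric
estimates at small n) receive an affirming PE sentence in an imaging-type
note dated ≥2 days after admission — the synthetic-world *definition* of
hospital-acquired, stated here as a convention, not a clinical claim — plus
a consistent discharge-summary mention and, by default, longer stays
(mirroring the known length-of-stay association). Negatives receive
confounders at configurable per-category rates (default 2% each): negated
mentions, historical PEs, PEs present on admission, pulmonary-edema
mentions, and prophylactic-anticoagulation mentions.

Text is template-based, not neural: determinism and exact span bookkeeping
are worth more in a test fixture than linguistic realism. That choice has a
sharp consequence for interpretation: passing the end-to-end tests shows
the *plumbing* is correct — retrieval keeps planted evidence, prompts
assemble faithfully, classification and evaluation are exact — and that
failure modes land only where they were planted. It does not show that any
particular generation model reads real clinical prose correctly; that
requires a real backend behind the same contracts and a reviewed cohort.

The mock backend's rules are deliberately imperfect in two documented ways
(it conflates pulmonary edema with PE, and reads assertive prophylaxis
mentions as diagnoses) while handling negation cues and admission-day
timing correctly. This reproduces the reported error taxonomy for this
task — terminology confusion and treatment overgeneralisation dominate
false positives — and makes every synthetic false positive attributable to
a named confounder category.

## Triplets and embedding backends

`build_triplets()` manufactures (anchor, positive, negative) training and
evaluation units: anchors are keyword chunks from gold-positive charts,
positives are other keyword chunks (same chart preferred), negatives are
either keyword-free chunks from keyword-free negative charts or the anchor
prefixed with a fixed negating clause. The template negator replaces
model-generated negations to keep the dataset deterministic and
dependency-free; a model-backed negator can be substituted through the
backend contract. `triplet_accuracy()` scores a backend by the fraction of
triplets with `cos(anchor, positive) > cos(anchor, negative)`, ties
counting as failures.

The shipped default embedder is a feature-hashing bag-of-words model:
deterministic, fast, adequate for lexical retrieval. On negated-anchor
triplets it scores near chance *by construction* — the negated anchor
contains the anchor verbatim, and a bag of words cannot see the negation —
which is precisely the gap that motivates fine-tuning a neural sentence
embedder on such triplets. Trained embedders plug in via
`embedding_backend()` without touching the pipeline.

## Problem sizes used by the test suite

The suite exercises end-to-end recovery at 5 000 charts (clean and
confounded), oracle equivalence on randomized corpora up to 10 000
patients and 200 chunks, bootstrap behavior over 100 seeded toy corpora at
1 000 resamples, and surveillance behavior over 20 generator seeds at
1 000 charts each; these sizes give stable checks at desk scale while the
defaults (`n_boot = 10000`, prevalence 0.004) remain the recommended
analysis settings.

## Known limitations

* The exemplar sentences, keyword variants beyond the six defaults, and
  detection prompt wording are authored configuration; treat them as
  starting points, not validated instruments.
* The hashing embedder measures lexical overlap, not meaning; semantic
  retrieval quality on real prose depends on substituting a trained
  embedder.
* The mock backend is a test oracle, not a model of LLM behavior; absolute
  metric values on synthetic corpora say nothing about real-cohort
  performance.
* Timestamps are timezone-naive (a uniform source-EMR timezone is
  assumed), and the corpus format holds one admission per patient —
  multi-admission linkage is out of scope.
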