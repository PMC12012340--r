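# PEAE detection: assemble per-patient evidence into a dialect-correct
# prompt, obtain a generated answer through a backend contract, and classify
# it with the first-sentence yes/no heuristic.

DIALECTS <- list(
  plain = list(prefix = "", suffix = ""),
  llama3 = list(
    prefix = "<|begin_of_text|><|start_header_id|>user<|end_header_id|>\n\n",
    suffix = "<|eot_id|><|start_header_id|>assistant<|end_header_id|>\n\n"),
  mistral = list(prefix = "[INST] ", suffix = " [/INST]"),
  gemma = list(prefix = "<start_of_turn>user\n",
               suffix = "<end_of_turn>\n<start_of_turn>model\n"),
  phi3 = list(prefix = "<|im_start|>user\n",
              suffix = "<|im_end|>\n<|im_start|>assistant\n"))

#' Prompt dialect for a model family
#'
#' Different instruction-tuned model families require different chat
#' delimiters (e.g. `[INST]` instruction tags vs `<|im_start|>` role
#' markers). A dialect wraps the user payload in a fixed prefix/suffix, so
#' the payload is always recoverable verbatim from the wrapped prompt.
#'
#' @param name One of `"llama3"`, `"mistral"`, `"gemma"`, `"phi3"`,
#'   `"plain"`.
#' @return An object of class `prompt_dialect`.
#' @export
prompt_dialect <- function(name = c("plain", "llama3", "mistral", "gemma",
                                    "phi3")) {
  name <- match.arg(name)
  structure(c(list(name = name), DIALECTS[[name]]), class = "prompt_dialect")
}

as_dialect <- function(x) {
  if (inherits(x, "prompt_dialect")) x else prompt_dialect(x)
}

#' Wrap a payload in a dialect's delimiters
#'
#' @param payload User message text.
#' @param dialect A [prompt_dialect()] or dialect name.
#' @return The wrapped prompt.
#' @export
wrap_dialect <- function(payload, dialect = "plain") {
  d <- as_dialect(dialect)
  paste0(d$prefix, payload, d$suffix)
}

#' Recover the user payload from a wrapped prompt
#'
#' @param prompt A prompt produced by [wrap_dialect()].
#' @param dialect The dialect it was wrapped with.
#' @return The original payload.
#' @export
unwrap_dialect <- function(prompt, dialect = "plain") {
  d <- as_dialect(dialect)
  out <- prompt
  if (nzchar(d$prefix) && startsWith(out, d$prefix)) {
    out <- substr(out, nchar(d$prefix) + 1L, nchar(out))
  }
  if (nzchar(d$suffix) && endsWith(out, d$suffix)) {
    out <- substr(out, 1L, nchar(out) - nchar(d$suffix))
  }
  out
}

#' Construct a generation backend
#'
#' A generation backend maps a non-empty prompt to generated text. The
#' package ships the deterministic [mock_generation_backend()]; adapters for
#' hosted chat models can implement the same contract.
#'
#' @param name,version Identity metadata recorded in artifacts.
#' @param generate `function(prompt) -> character(1)`.
#' @return An object of class `generation_backend`.
#' @export
generation_backend <- function(name, version, generate) {
  stopifnot(is.function(generate))
  structure(list(name = name, version = version, generate = generate),
            class = "generation_backend")
}

# ---- evidence bundle & detection prompt ------------------------------------

#' Bundle the per-patient material for detection
#'
#' @param patient_id Patient identifier.
#' @param chunks Evidence chunk data frame (re-sorted by timestamp).
#' @param discharge_info Optional [discharge_info()].
#' @param admission_date,discharge_date Stay dates (admission must not
#'   follow discharge).
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(patient_id, chunks, discharge_info = NULL,
                            admission_date, discharge_date) {
  admission_date <- as.Date(admission_date)
  discharge_date <- as.Date(discharge_date)
  stopifnot(admission_date <= discharge_date)
  if (nrow(chunks)) chunks <- chunks[order(chunks$timestamp), , drop = FALSE]
  if (!is.null(discharge_info)) stopifnot(inherits(discharge_info,
                                                   "discharge_info"))
  structure(list(patient_id = as.character(patient_id), chunks = chunks,
                 discharge_info = discharge_info,
                 admission_date = admission_date,
                 discharge_date = discharge_date),
            class = "evidence_bundle")
}

NO_EVIDENCE_PLACEHOLDER <- "No PE-related text was retrieved for this patient."

evidence_line <- function(chunks, i) {
  sprintf("[%s] (%s %s) %s",
          format(chunks$timestamp[i], "%Y-%m-%d %H:%M"),
          chunks$note_id[i], chunks$chunk_index[i],
          gsub("\n", " ", chunks$text[i]))
}

#' Build the PEAE detection prompt
#'
#' The payload contains, in order: the task instruction (did a PE develop
#' after admission as a hospital-acquired adverse event, as opposed to being
#' present on admission or historical), the temporal facts, the dated
#' evidence chunks oldest first, the recovered discharge sections (when
#' requested and available), and the output instruction to answer "yes" or
#' "no" first and then justify. The dialect wrapping is applied last. When
#' the evidence budget `max_chars` is finite, oldest evidence lines are
#' dropped first until the evidence section fits; the number of dropped
#' lines is recorded in the result's `truncated` attribute.
#'
#' @param bundle An [evidence_bundle()].
#' @param dialect A [prompt_dialect()] or name.
#' @param include_discharge Include the discharge section when its status is
#'   not `"failed"`.
#' @param max_chars Character budget for the evidence section (default
#'   `Inf`).
#' @return The wrapped prompt, with attribute `truncated` (dropped line
#'   count).
#' @export
build_detection_prompt <- function(bundle, dialect = "plain",
                                   include_discharge = TRUE,
                                   max_chars = Inf) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  instruction <- paste0(
    "You are reviewing the hospital chart of one admission. Decide whether ",
    "the patient developed a pulmonary embolism (PE) as a hospital-acquired ",
    "adverse event: the PE must have developed after admission; a PE that ",
    "was present on admission, community-acquired, or purely historical ",
    "does not count.")
  temporal <- paste0("--- TEMPORAL FACTS ---\n",
                     "Admission date: ", iso_date(bundle$admission_date), "\n",
                     "Discharge date: ", iso_date(bundle$discharge_date))
  dropped <- 0L
  if (nrow(bundle$chunks)) {
    lines <- vapply(seq_len(nrow(bundle$chunks)),
                    function(i) evidence_line(bundle$chunks, i), character(1))
    while (length(lines) > 1L &&
           sum(nchar(lines)) + length(lines) - 1L > max_chars) {
      lines <- lines[-1L]   # oldest first
      dropped <- dropped + 1L
    }
    evidence <- paste0("--- PE EVIDENCE ---\n", paste(lines, collapse = "\n"))
  } else {
    evidence <- paste0("--- PE EVIDENCE ---\n", NO_EVIDENCE_PLACEHOLDER)
  }
  sections <- c(instruction, temporal, evidence)
  di <- bundle$discharge_info
  if (include_discharge && !is.null(di) && di$status != "failed") {
    keys <- discharge_section_keys()
    body <- paste(sprintf("%s: %s", unname(keys),
                          vapply(names(keys), function(k) di[[k]],
                                 character(1))),
                  collapse = "\n")
    sections <- c(sections, paste0("--- DISCHARGE INFORMATION ---\n", body))
  }
  sections <- c(sections, paste0(
    "--- OUTPUT INSTRUCTION ---\n",
    "Answer with \"yes\" or \"no\" in your first sentence, then justify ",
    "your answer from the evidence."))
  prompt <- wrap_dialect(paste(sections, collapse = "\n\n"), dialect)
  attr(prompt, "truncated") <- dropped
  prompt
}

#' Classify a generated answer with the first-sentence yes/no heuristic
#'
#' The first sentence is the text up to the first `.`, `!`, `?` or newline;
#' the label is 1 iff it contains the word "yes" (case-insensitive, word
#' boundaries, so "yesterday" never matches); the justification is the
#' trimmed remainder. Empty input yields label 0 with `flagged = TRUE`.
#'
#' @param raw Generated text.
#' @return List with `label` (0/1), `justification`, `flagged`.
#' @export
#' @examples
#' classify_response("Yes. The CTPA on day 5 confirms a new PE.")
classify_response <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    return(list(label = 0L, justification = "", flagged = TRUE))
  }
  pos <- regexpr("[.!?\n]", raw)
  if (pos == -1L) {
    first <- raw; rest <- ""
  } else {
    first <- substr(raw, 1L, pos)
    rest <- substr(raw, pos + 1L, nchar(raw))
  }
  label <- if (grepl("\\byes\\b", first, ignore.case = TRUE, perl = TRUE))
    1L else 0L
  list(label = label, justification = trimws(rest), flagged = FALSE)
}

# ---- mock generation backend ------------------------------------------------

#' Rules for the mock generation backend
#'
#' The mock backend answers detection prompts from deterministic rules over
#' the prompt payload. A sentence affirms a qualifying PE when it contains a
#' PE-ish term and an assertion verb, has no negation cue earlier in the
#' sentence, and its evidence line is dated at least `min_days` days after
#' the stated admission date (the synthetic-world convention for
#' "hospital-acquired"). Two deliberate imperfections emulate the error
#' modes reported for instruction-tuned models on this task: the term
#' pattern conflates "pulmonary edema" with PE (terminology confusion), and
#' prophylactic-anticoagulation mentions phrased assertively are taken as
#' evidence (treatment overgeneralisation). Both are configurable.
#'
#' @param term_pattern Regex for PE-ish terms (case-insensitive).
#' @param assertion_pattern Regex for assertion verbs (case-insensitive).
#' @param negation_cues Cue words/phrases that defeat an in-sentence match
#'   when they appear before the term.
#' @param min_days Days after admission before evidence counts as
#'   hospital-acquired (default 2).
#' @return An object of class `mock_rule_config`.
#' @export
mock_rule_config <- function(
    term_pattern = "pulmonary embol[a-z]*|pulmonary edema|\\bPE\\b|\\bCTPE\\b|blood clot",
    assertion_pattern = "demonstrat|confirm|identif|diagnos|positive for|developed|noted|shows|read as|consistent with|prophylaxis",
    negation_cues = c("no", "not", "ruled out", "history of"),
    min_days = 2L) {
  structure(list(term_pattern = term_pattern,
                 assertion_pattern = assertion_pattern,
                 negation_cues = negation_cues,
                 min_days = as.integer(min_days)),
            class = "mock_rule_config")
}

# does this sentence affirm a (rule-world) PE? negation cue must not precede
# the term within the sentence
sentence_affirms <- function(sentence, rules) {
  tp <- regexpr(rules$term_pattern, sentence, ignore.case = TRUE, perl = TRUE)
  if (tp == -1L) return(FALSE)
  if (!grepl(rules$assertion_pattern, sentence, ignore.case = TRUE,
             perl = TRUE)) {
    return(FALSE)
  }
  before <- substr(sentence, 1L, tp - 1L)
  cue_re <- paste0("\\b(", paste(regex_escape(rules$negation_cues),
                                 collapse = "|"), ")\\b")
  !grepl(cue_re, before, ignore.case = TRUE, perl = TRUE)
}

mock_answer_detection <- function(payload, rules) {
  adm <- regmatches(payload,
                    regexpr("Admission date: \\d{4}-\\d{2}-\\d{2}", payload))
  adm_date <- if (length(adm)) as.Date(sub("Admission date: ", "", adm)) else NA
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  ev <- regmatches(lines,
                   regexec("^\\[(\\d{4}-\\d{2}-\\d{2}) \\d{2}:\\d{2}\\] \\([^)]*\\) (.*)$",
                           lines))
  ev <- Filter(function(x) length(x) == 3L, ev)
  for (e in ev) {
    ev_date <- as.Date(e[2])
    if (!is.na(adm_date) &&
        as.integer(ev_date - adm_date) < rules$min_days) {
      next   # present on (or too near) admission: not hospital-acquired
    }
    sentences <- strsplit(e[3], "(?<=[.!?;])\\s+", perl = TRUE)[[1]]
    for (s in sentences) {
      if (sentence_affirms(s, rules)) {
        return(paste0("Yes. Evidence dated ", e[2],
                      " indicates a pulmonary embolism that developed ",
                      "during the stay: \"", trimws(s), "\""))
      }
    }
  }
  paste0("No. No qualifying evidence of a hospital-acquired pulmonary ",
         "embolism was found in the retrieved chart material.")
}

mock_answer_discharge <- function(payload) {
  m <- regexec("--- DISCHARGE SUMMARY ---\n(.*)\n--- END DISCHARGE SUMMARY ---",
               payload)
  hit <- regmatches(payload, m)[[1]]
  if (length(hit) < 2L) return("")
  summary_text <- hit[2]
  keys <- discharge_section_keys()
  vals <- lapply(unname(keys), function(k) {
    pat <- paste0("(?mi)^", gsub(" ", "[ _]+", regex_escape(k)),
                  "\\s*:\\s*(.*)$")
    mm <- regmatches(summary_text, regexpr(pat, summary_text, perl = TRUE))
    if (!length(mm)) return("")
    trimws(sub("(?mi)^[^:]*:\\s*", "", mm, perl = TRUE))
  })
  as.character(jsonlite::toJSON(stats::setNames(vals, unname(keys)),
                                auto_unbox = TRUE, digits = NA))
}

#' Deterministic mock generation backend
#'
#' A rule-based stand-in for an instruction-tuned chat model, used to
#' exercise the whole pipeline deterministically. Detection prompts are
#' answered "Yes."/"No." by scanning the evidence section under
#' [mock_rule_config()]; discharge-extraction prompts are answered by
#' echoing the labelled sections of the embedded summary as a JSON block.
#'
#' @param rules A [mock_rule_config()].
#' @return A [generation_backend()] named `"rule-mock"`.
#' @export
mock_generation_backend <- function(rules = mock_rule_config()) {
  stopifnot(inherits(rules, "mock_rule_config"))
  generate <- function(prompt) {
    stopifnot(is.character(prompt), length(prompt) == 1L, nzchar(prompt))
    if (grepl("--- DISCHARGE SUMMARY ---", prompt, fixed = TRUE)) {
      mock_answer_discharge(prompt)
    } else {
      mock_answer_detection(prompt, rules)
    }
  }
  generation_backend("rule-mock", "1", generate)
}

# ---- end-to-end detection ---------------------------------------------------

#' Detection pipeline configuration
#'
#' @param method Evidence retrieval: `"keyword"` or `"semantic"`.
#' @param include_discharge Feed recovered discharge sections to the
#'   detection prompt.
#' @param dialect Prompt dialect name.
#' @param spec A [keyword_spec()].
#' @param strategy,max_words,overlap Chunking parameters.
#' @param examples,emb_backend,sem_config Semantic retrieval parameters.
#' @param max_chars Evidence character budget (oldest dropped first).
#' @param lenient Record backend failures as label-0 flagged results instead
#'   of aborting the corpus run.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(method = c("keyword", "semantic"),
                             include_discharge = TRUE, dialect = "plain",
                             spec = keyword_spec(), strategy = "paragraph",
                             max_words = 128L, overlap = 0L,
                             examples = example_sentences(),
                             emb_backend = hash_embedding_backend(),
                             sem_config = semantic_filter_config(),
                             max_chars = Inf, lenient = FALSE) {
  structure(list(method = match.arg(method),
                 include_discharge = isTRUE(include_discharge),
                 dialect = dialect, spec = spec, strategy = strategy,
                 max_words = max_words, overlap = overlap,
                 examples = examples, emb_backend = emb_backend,
                 sem_config = sem_config, max_chars = max_chars,
                 lenient = isTRUE(lenient)),
            class = "detection_config")
}

#' Detect PEAE for one chart
#'
#' Runs the full per-patient flow: evidence extraction, optional discharge
#' information extraction, detection prompt construction, generation, and
#' first-sentence classification.
#'
#' @param chart A [patient_chart()] with at least one note.
#' @param config A [detection_config()].
#' @param backend A [generation_backend()].
#' @param chunks Optional precomputed evidence chunks (from
#'   [extract_evidence()] with the same configuration); extracted here when
#'   `NULL`.
#' @return An object of class `detection_result`: `patient_id`, `label`,
#'   `raw_response`, `justification`, `prompt_hash`, `flagged`.
#' @export
detect_peae <- function(chart, config = detection_config(),
                        backend = mock_generation_backend(),
                        chunks = NULL) {
  stopifnot(inherits(chart, "patient_chart"),
            inherits(config, "detection_config"),
            inherits(backend, "generation_backend"))
  if (!length(chart$notes)) {
    stop("detect_peae: chart ", chart$patient_id, " has no notes")
  }
  if (is.null(chunks)) {
    chunks <- extract_evidence(chart, method = config$method,
                               spec = config$spec,
                               strategy = config$strategy,
                               max_words = config$max_words,
                               overlap = config$overlap,
                               examples = config$examples,
                               backend = config$emb_backend,
                               config = config$sem_config)
  }
  di <- NULL
  if (config$include_discharge && !is.null(chart$discharge_summary)) {
    di <- extract_discharge_info(chart, backend, config$dialect)
  }
  bundle <- evidence_bundle(chart$patient_id, chunks, di,
                            chart$admission_date, chart$discharge_date)
  prompt <- build_detection_prompt(bundle, config$dialect,
                                   config$include_discharge,
                                   config$max_chars)
  raw <- tryCatch(backend$generate(prompt), error = function(e) e)
  if (inherits(raw, "error")) {
    if (!config$lenient) {
      stop("detect_peae: backend failure for patient ", chart$patient_id,
           ": ", conditionMessage(raw))
    }
    raw <- ""
  }
  cls <- classify_response(raw)
  structure(list(patient_id = chart$patient_id, label = cls$label,
                 raw_response = if (is.character(raw)) raw else "",
                 justification = cls$justification,
                 prompt_hash = fingerprint(as.character(prompt)),
                 flagged = cls$flagged),
            class = "detection_result")
}

#' Detect PEAE over a whole corpus
#'
#' @param corpus A [chart_corpus()].
#' @param config A [detection_config()].
#' @param backend A [generation_backend()].
#' @return Data frame with one row per chart: `patient_id`, `label`, `gold`,
#'   `prompt_hash`, `flagged`, `backend`.
#' @export
detect_corpus <- function(corpus, config = detection_config(),
                          backend = mock_generation_backend()) {
  stopifnot(inherits(corpus, "chart_corpus"))
  rows <- lapply(corpus$charts, function(ch) {
    r <- detect_peae(ch, config, backend)
    data.frame(patient_id = r$patient_id, label = r$label,
               gold = ch$gold_label %||% NA_integer_,
               prompt_hash = r$prompt_hash, flagged = r$flagged,
               backend = backend$name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
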