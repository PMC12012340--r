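# Synthetic chart corpus generator: gold-labelled admissions with planted
# PE evidence, planted confounders, six-section discharge summaries and
# coded diagnoses, so every pipeline stage is testable without real data.

#' The synthetic note-type vocabulary
#'
#' 120 note-type labels (20 base genres crossed with 6 qualifiers),
#' mirroring the large note-type vocabularies of hospital EMRs.
#'
#' @return Character vector of 120 labels.
#' @export
note_type_vocabulary <- function() {
  base <- c("progress note", "nursing note", "physician note",
            "consultation", "diagnostic imaging report", "laboratory report",
            "operative report", "emergency department note",
            "physiotherapy note", "pharmacy note", "social work note",
            "respiratory therapy note", "cardiology consult",
            "dietitian note", "wound care note", "anesthesia record",
            "triage note", "transfer summary", "code status note",
            "care plan")
  qual <- c("", " addendum", " follow-up", " interim", " final",
            " preliminary")
  as.vector(outer(base, qual, paste0))
}

# sentence templates; {slot} placeholders are filled by plant_sentence
PEAE_TEMPLATES <- list(
  affirm_ctpa = "CTPA demonstrates acute pulmonary embolism in the {lobe} lobe.",
  affirm_ct = "CT chest confirmed a new PE involving the {side} pulmonary artery.",
  affirm_vq = "VQ scan read as high probability for pulmonary embolism.",
  negated_pe = "CTPA shows no evidence of pulmonary embolism.",
  historical_pe = "History of pulmonary embolism in {year}, treated and resolved.",
  pulmonary_edema = "Chest radiograph demonstrates pulmonary edema with bilateral effusions.",
  prophylaxis_mention = "Daily enoxaparin noted for blood clot prophylaxis.")

#' Sentence templates used by the generator
#'
#' @return Named list of template strings with `{slot}` placeholders.
#' @export
peae_templates <- function() PEAE_TEMPLATES

FILLER_SENTENCES <- c(
  "Vital signs stable overnight.",
  "Patient ambulating in the hallway with assistance.",
  "Diet advanced as tolerated.",
  "Pain well controlled on current regimen.",
  "Family meeting held to discuss goals of care.",
  "Electrolytes within normal limits this morning.",
  "Wound edges clean and dry, dressing changed.",
  "Physiotherapy session completed at bedside.",
  "Sleeping comfortably at time of rounds.",
  "Plan reviewed with the attending physician.",
  "Urine output adequate over the last shift.",
  "Oxygen weaned to room air without desaturation.")

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the cohort shape the screening framework targets: a rare
#' event (0.4% prevalence), admissions spanning 2017-2022, a dozen active
#' note types drawn from a 120-type vocabulary, several notes per stay, and
#' longer stays for true PEAE cases. Confounder rates control how often a
#' gold-negative chart carries a planted look-alike: a negated PE mention, a
#' historical PE, a PE documented as present on admission, a pulmonary-edema
#' mention, or an anticoagulant-prophylaxis mention.
#'
#' @param n_patients Number of charts.
#' @param prevalence Gold-positive proportion (default 0.004).
#' @param date_range Two admission dates bounding the corpus.
#' @param note_types Note-type labels to sample from; `NULL` draws 12 from
#'   [note_type_vocabulary()] under the seed.
#' @param notes_lambda Poisson mean of extra notes per stay (min 1 note).
#' @param confounder_rates Named per-category rates, see Details.
#' @param los_shift_for_positives Give positives longer stays (the known
#'   association between PEAE and length of stay).
#' @param icd_miss_rate Probability a true PEAE lacks a post-admission I26
#'   code (drives the ICD baseline's imperfect sensitivity).
#' @param icd_miscode_rate Probability a plain negative chart carries a
#'   spurious post-admission I26 code.
#' @param seed Integer seed; the generator is fully deterministic under it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000L, prevalence = 0.004,
                             date_range = c("2017-01-01", "2022-12-31"),
                             note_types = NULL, notes_lambda = 4,
                             confounder_rates = c(negated_pe = 0.02,
                                                  historical_pe = 0.02,
                                                  poa_pe = 0.02,
                                                  pulmonary_edema = 0.02,
                                                  prophylaxis_mention = 0.02),
                             los_shift_for_positives = TRUE,
                             icd_miss_rate = 0.5, icd_miscode_rate = 0.003,
                             seed = 1L) {
  stopifnot(n_patients >= 0, prevalence >= 0, prevalence <= 1,
            all(confounder_rates >= 0), all(confounder_rates <= 1),
            icd_miss_rate >= 0, icd_miss_rate <= 1)
  full <- c(negated_pe = 0, historical_pe = 0, poa_pe = 0,
            pulmonary_edema = 0, prophylaxis_mention = 0)
  full[names(confounder_rates)] <- confounder_rates
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 date_range = as.Date(date_range),
                 note_types = note_types, notes_lambda = notes_lambda,
                 confounder_rates = full,
                 los_shift_for_positives = isTRUE(los_shift_for_positives),
                 icd_miss_rate = icd_miss_rate,
                 icd_miscode_rate = icd_miscode_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

render_template <- function(template_id, slots = list()) {
  tpl <- PEAE_TEMPLATES[[template_id]]
  if (is.null(tpl)) stop("unknown template: ", template_id)
  need <- regmatches(tpl, gregexpr("\\{[a-z_]+\\}", tpl))[[1]]
  for (ph in need) {
    slot <- substr(ph, 2, nchar(ph) - 1L)
    if (is.null(slots[[slot]])) stop("missing slot '", slot,
                                     "' for template ", template_id)
    tpl <- sub(ph, slots[[slot]], tpl, fixed = TRUE)
  }
  tpl
}

#' Insert a template sentence into a note, recording its exact span
#'
#' @param template_id Name from [peae_templates()].
#' @param slots Named list of slot values.
#' @param note A [clinical_note()].
#' @param position 0-based character offset at which to insert (defaults to
#'   the end of the note); beyond the text length is an error.
#' @return List with the updated `note`, the 0-based half-open `span` of the
#'   inserted sentence, and its `text`.
#' @export
plant_sentence <- function(template_id, slots = list(), note,
                           position = nchar(note$text)) {
  sentence <- render_template(template_id, slots)
  n <- nchar(note$text)
  if (position < 0 || position > n) {
    stop("plant_sentence: position ", position, " outside text of length ", n)
  }
  new_text <- paste0(substr(note$text, 1, position), sentence,
                     substr(note$text, position + 1L, n))
  note$text <- new_text
  note$empty_flagged <- FALSE
  list(note = note, span = c(position, position + nchar(sentence)),
       text = sentence)
}

filler_paragraphs <- function(n_sentences) {
  s <- sample(FILLER_SENTENCES, n_sentences, replace = TRUE)
  paste(s, collapse = "\n\n")
}

day_time <- function(admission, day) {
  as.POSIXct(admission, tz = "UTC") + day * 86400 +
    round(stats::runif(1, 8, 16)) * 3600
}

synth_discharge_summary <- function(pid, discharge_date, label, event_day,
                                    confs) {
  findings <- if (label == 1L) {
    sprintf("Hospital course complicated by pulmonary embolism on day %d, therapeutic anticoagulation started.",
            event_day)
  } else if ("negated_pe" %in% confs) {
    "PE was suspected but imaging showed no evidence of pulmonary embolism."
  } else {
    "Course uncomplicated; symptoms improved with supportive care."
  }
  history <- if ("historical_pe" %in% confs) {
    "Remote history of pulmonary embolism, long since resolved."
  } else {
    "Hypertension and type 2 diabetes."
  }
  text <- paste(
    sprintf("Reason for Hospitalization: %s",
            resample1(c("Community-acquired pneumonia.", "Elective hip arthroplasty.",
                        "Congestive heart failure exacerbation.", "Abdominal pain under investigation."))),
    sprintf("Significant Findings for the Current Admission: %s", findings),
    sprintf("Procedures and Treatments Provided: %s",
            resample1(c("Intravenous antibiotics and supportive care.",
                        "Surgical repair with routine postoperative care.",
                        "Diuresis and cardiac monitoring."))),
    sprintf("Medical History: %s", history),
    sprintf("Discharge Condition: %s",
            resample1(c("Stable, ambulating independently.",
                        "Improved, afebrile at discharge."))),
    sprintf("Patient and Family Instructions: %s",
            resample1(c("Follow up with family physician in two weeks.",
                        "Return to hospital if symptoms worsen."))),
    sep = "\n\n")
  clinical_note(paste0(pid, "-ds"), "discharge summary",
                as.POSIXct(discharge_date, tz = "UTC") + 17 * 3600, text)
}

empty_span_df <- function() {
  data.frame(note_id = character(0), start = integer(0), end = integer(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             template = character(0), category = character(0),
             text = character(0), stringsAsFactors = FALSE)
}

span_row <- function(note_id, span, timestamp, template, category, text) {
  data.frame(note_id = note_id, start = span[1], end = span[2],
             timestamp = timestamp, template = template, category = category,
             text = text, stringsAsFactors = FALSE)
}

synth_chart <- function(i, cfg, note_types) {
  pid <- sprintf("P%06d", i)
  label <- stats::rbinom(1, 1, cfg$prevalence)
  span_days <- as.integer(cfg$date_range[2] - cfg$date_range[1])
  admission <- cfg$date_range[1] + sample.int(span_days + 1L, 1L) - 1L
  los <- if (label == 1L && cfg$los_shift_for_positives) {
    4L + stats::rpois(1, 8)
  } else if (label == 1L) {
    max(3L, 1L + stats::rpois(1, 3))
  } else {
    1L + stats::rpois(1, 3)
  }
  discharge <- admission + los
  n_notes <- 1L + stats::rpois(1, cfg$notes_lambda)
  notes <- lapply(seq_len(n_notes), function(j) {
    day <- stats::runif(1, 0, los)
    clinical_note(sprintf("%s-n%02d", pid, j), resample1(note_types),
                  as.POSIXct(admission, tz = "UTC") + round(day * 86400),
                  filler_paragraphs(1L + stats::rpois(1, 2)))
  })
  evidence <- empty_span_df()
  confounders <- empty_span_df()
  confs <- character(0)
  event_day <- NA_integer_

  add_planted <- function(template, slots, day, category) {
    nid <- sprintf("%s-x%s", pid, substr(category, 1, 3))
    note <- clinical_note(nid,
                          if (startsWith(category, "affirm"))
                            "diagnostic imaging report"
                          else resample1(note_types),
                          day_time(admission, day),
                          filler_paragraphs(1L))
    note$text <- paste0(note$text, "\n\n")
    planted <- plant_sentence(template, slots, note)
    list(note = planted$note,
         row = span_row(nid, planted$span, planted$note$timestamp, template,
                        category, planted$text))
  }

  if (label == 1L) {
    event_day <- if (los <= 2L) 2L else resample1(2:los)
    tpl <- resample1(c("affirm_ctpa", "affirm_ct", "affirm_vq"))
    slots <- list(lobe = resample1(c("right lower", "left lower",
                                     "right upper")),
                  side = resample1(c("right", "left")))
    p <- add_planted(tpl, slots, event_day, "affirm_evidence")
    notes <- c(notes, list(p$note))
    evidence <- rbind(evidence, p$row)
  } else {
    rates <- cfg$confounder_rates
    draw <- stats::runif(length(rates)) < rates
    confs <- names(rates)[draw]
    for (cf in confs) {
      day <- switch(cf,
                    poa_pe = 0L,
                    if (los >= 2L) resample1(2:los) else los)
      p <- switch(cf,
        poa_pe = add_planted("affirm_ctpa",
                             list(lobe = "right lower"), day, cf),
        negated_pe = add_planted("negated_pe", list(), day, cf),
        historical_pe = add_planted("historical_pe",
                                    list(year = as.character(
                                      1999L + sample.int(15L, 1L))), day, cf),
        pulmonary_edema = add_planted("pulmonary_edema", list(), day, cf),
        prophylaxis_mention = add_planted("prophylaxis_mention", list(), day,
                                          cf))
      notes <- c(notes, list(p$note))
      confounders <- rbind(confounders, p$row)
    }
  }

  # coded diagnoses consistent with the label, imperfect on purpose
  other_pool <- c("E11.9", "I10", "J18.9", "N17.9", "K21.9", "M17.1",
                  "F03", "C34.1")
  codes <- sample(other_pool, 1L + stats::rbinom(1, 2, 0.5))
  poa <- rep(TRUE, length(codes))
  if (label == 1L) {
    if (stats::runif(1) >= cfg$icd_miss_rate) {
      codes <- c(codes, "I26.9"); poa <- c(poa, FALSE)
    }
  } else {
    if ("poa_pe" %in% confs) {
      codes <- c(codes, "I26.0"); poa <- c(poa, TRUE)
    } else if (stats::runif(1) < cfg$icd_miscode_rate) {
      codes <- c(codes, "I26.9"); poa <- c(poa, FALSE)
    }
  }

  chart <- patient_chart(
    patient_id = pid, admission_date = admission, discharge_date = discharge,
    notes = notes,
    discharge_summary = synth_discharge_summary(pid, discharge, label,
                                                event_day, confs),
    diagnosis_codes = diagnosis_codes(codes, poa),
    gold_label = label,
    age = 17L + sample.int(83L, 1L),
    sex = resample1(c("F", "F", "M", "M", "F")),
    died_in_hospital = stats::runif(1) < (if (label == 1L) 0.125 else 0.07),
    n_comorbidities = stats::rbinom(1, 4, 0.35))
  annotation <- structure(list(patient_id = pid, label = label,
                               event_day = event_day,
                               planted_evidence = evidence,
                               planted_confounders = confounders),
                          class = "gold_annotation")
  list(chart = chart, annotation = annotation)
}

#' Generate a gold-labelled synthetic chart corpus
#'
#' Every chart receives filler notes, a six-section discharge summary and
#' coded diagnoses. Gold positives get an affirming PE sentence planted in a
#' diagnostic-imaging note dated at least 2 days after admission (the
#' synthetic-world convention for "hospital-acquired") plus a consistent
#' discharge-summary mention and, optionally, a longer stay. Gold negatives
#' receive confounders at the configured per-category rates. Identical
#' configurations produce byte-identical corpora.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a [chart_corpus()]) and `annotations` (named
#'   list of `gold_annotation` records: planted evidence and confounder
#'   spans with timestamps).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    note_types <- config$note_types %||%
      sample(note_type_vocabulary(), 12L)
    out <- lapply(seq_len(config$n_patients), synth_chart, cfg = config,
                  note_types = note_types)
    charts <- lapply(out, `[[`, "chart")
    annotations <- lapply(out, `[[`, "annotation")
    names(annotations) <- vapply(charts, `[[`, character(1), "patient_id")
    list(corpus = chart_corpus(charts, source = "synthetic",
                               seed = config$seed),
         annotations = annotations)
  })
}

#' Summarize a generated corpus against its annotations
#'
#' @param corpus A [chart_corpus()] from [generate_corpus()].
#' @param annotations The matching annotation list.
#' @return List: `n_patients`, `realized_prevalence`, `confounder_counts`
#'   (per category), `admissions_per_year`, `seed`.
#' @export
corpus_report <- function(corpus, annotations) {
  stopifnot(inherits(corpus, "chart_corpus"))
  ids <- vapply(corpus$charts, `[[`, character(1), "patient_id")
  if (!identical(sort(ids), sort(names(annotations)))) {
    stop("corpus_report: corpus and annotations cover different patients")
  }
  labels <- corpus_gold_labels(corpus)
  cats <- c("negated_pe", "historical_pe", "poa_pe", "pulmonary_edema",
            "prophylaxis_mention")
  conf_counts <- stats::setNames(integer(length(cats)), cats)
  for (a in annotations) {
    if (nrow(a$planted_confounders)) {
      t <- table(a$planted_confounders$category)
      conf_counts[names(t)] <- conf_counts[names(t)] + as.integer(t)
    }
  }
  years <- vapply(corpus$charts,
                  function(ch) format(ch$admission_date, "%Y"), character(1))
  list(n_patients = length(ids),
       realized_prevalence = if (length(ids)) mean(labels == 1L) else NA_real_,
       confounder_counts = as.list(conf_counts),
       admissions_per_year = as.list(table(years)),
       seed = corpus$metadata$seed)
}

#' Which charts carry a planted confounder?
#'
#' @param annotations Annotation list from [generate_corpus()].
#' @return Named logical vector keyed by patient id.
#' @export
has_confounder <- function(annotations) {
  vapply(annotations, function(a) nrow(a$planted_confounders) > 0L,
         logical(1))
}
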