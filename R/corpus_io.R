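#' Construct a clinical note
#'
#' A single timestamped free-text document from one hospitalization, e.g. a
#' nursing note, progress note or diagnostic imaging report. Real inpatient
#' records span a large vocabulary of note types (on the order of a hundred
#' or more distinct types); `note_type` is an uncontrolled string here.
#'
#' @param note_id Opaque identifier, unique within the chart.
#' @param note_type Note-type label (e.g. `"nursing"`, `"imaging"`).
#' @param timestamp `POSIXct` (or ISO-8601 string) time the note was written.
#' @param text Note body. Empty text is allowed only when
#'   `allow_empty = TRUE`, in which case the note carries an `empty_flagged`
#'   marker.
#' @param allow_empty Permit empty `text`.
#' @return An object of class `clinical_note`.
#' @export
#' @examples
#' clinical_note("n1", "imaging", "2020-05-03T10:00:00",
#'               "CTPA demonstrates acute pulmonary embolism.")
clinical_note <- function(note_id, note_type, timestamp, text,
                          allow_empty = FALSE) {
  if (is.character(timestamp)) timestamp <- parse_datetime(timestamp)
  stopifnot(inherits(timestamp, "POSIXct"), length(text) == 1L)
  text <- as.character(text)
  if (!nzchar(text) && !allow_empty) {
    stop("clinical_note: empty text (set allow_empty = TRUE to keep it)")
  }
  structure(
    list(note_id = as.character(note_id),
         note_type = as.character(note_type),
         timestamp = timestamp,
         text = text,
         empty_flagged = !nzchar(text)),
    class = "clinical_note")
}

#' Construct a set of coded discharge diagnoses
#'
#' ICD-10 codes as recorded in a discharge abstract, with the diagnosis-type
#' indicator reduced to a present-on-admission (POA) flag. POA conditions are
#' excluded from hospital-acquired status.
#'
#' @param code Character vector of ICD-10 codes (letter, digits, optional
#'   dotted subcode, e.g. `"I26.9"`).
#' @param present_on_admission Logical vector, recycled to `length(code)`.
#' @return A data frame with columns `code`, `present_on_admission`.
#' @export
diagnosis_codes <- function(code = character(0),
                            present_on_admission = logical(0)) {
  code <- as.character(code)
  if (length(code) && !all(grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code))) {
    bad <- code[!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code)]
    stop("invalid ICD-10 code(s): ", paste(bad, collapse = ", "))
  }
  if (length(code) && length(present_on_admission) == 0L) {
    present_on_admission <- FALSE
  }
  data.frame(code = code,
             present_on_admission = rep_len(as.logical(present_on_admission),
                                            length(code)),
             stringsAsFactors = FALSE)
}

#' Construct a patient chart
#'
#' One hospitalization: admission/discharge dates, the ordered collection of
#' clinical notes, an optional discharge summary (kept apart from the notes
#' because it is processed by its own extraction module), optional coded
#' diagnoses, an optional adjudicated gold label, and optional demographics
#' used only for cohort summarization.
#'
#' @param patient_id Opaque identifier, unique within a corpus.
#' @param admission_date,discharge_date `Date` (or `"YYYY-MM-DD"` strings);
#'   admission must not follow discharge.
#' @param notes List of [clinical_note()] objects; re-sorted by timestamp.
#' @param discharge_summary Optional [clinical_note()].
#' @param diagnosis_codes Optional data frame from [diagnosis_codes()].
#' @param gold_label Optional binary chart-review adjudication
#'   (1 = confirmed PEAE, 0 = non-PEAE, `NA` = unreviewed).
#' @param age,sex,died_in_hospital,n_comorbidities Optional demographics
#'   (`sex` one of `"F"`/`"M"`).
#' @return An object of class `patient_chart`.
#' @export
patient_chart <- function(patient_id, admission_date, discharge_date,
                          notes = list(), discharge_summary = NULL,
                          diagnosis_codes = NULL, gold_label = NA_integer_,
                          age = NA_integer_, sex = NA_character_,
                          died_in_hospital = NA, n_comorbidities = NA_integer_) {
  admission_date <- as.Date(admission_date)
  discharge_date <- as.Date(discharge_date)
  stopifnot(all(vapply(notes, inherits, logical(1), "clinical_note")))
  if (length(notes)) {
    ord <- order(vapply(notes, function(n) as.numeric(n$timestamp), numeric(1)))
    notes <- notes[ord]
  }
  if (!is.null(discharge_summary)) {
    stopifnot(inherits(discharge_summary, "clinical_note"))
  }
  structure(
    list(patient_id = as.character(patient_id),
         admission_date = admission_date,
         discharge_date = discharge_date,
         notes = notes,
         discharge_summary = discharge_summary,
         diagnosis_codes = diagnosis_codes,
         gold_label = if (is.na(gold_label)) NA_integer_ else as.integer(gold_label),
         age = as.integer(age),
         sex = as.character(sex),
         died_in_hospital = died_in_hospital,
         n_comorbidities = as.integer(n_comorbidities)),
    class = "patient_chart")
}

#' Construct a chart corpus
#'
#' @param charts List of [patient_chart()] objects; `patient_id` must be
#'   unique (when a patient has several admissions, keep one — conventionally
#'   the most recent — before building the corpus).
#' @param source Free-text provenance label.
#' @param seed Generation seed when the corpus is synthetic, else `NA`.
#' @return An object of class `chart_corpus`.
#' @export
chart_corpus <- function(charts = list(), source = "unknown", seed = NA) {
  stopifnot(all(vapply(charts, inherits, logical(1), "patient_chart")))
  ids <- vapply(charts, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(charts = charts,
                 metadata = list(schema_version = 1L,
                                 source = source, seed = seed)),
            class = "chart_corpus")
}

#' @export
length.chart_corpus <- function(x) length(x$charts)

#' @export
print.chart_corpus <- function(x, ...) {
  labs <- corpus_gold_labels(x)
  cat(sprintf("<chart_corpus> %d charts (source: %s)\n", length(x$charts),
              x$metadata$source))
  cat(sprintf("  gold labels: %d positive / %d negative / %d unlabelled\n",
              sum(labs == 1L, na.rm = TRUE), sum(labs == 0L, na.rm = TRUE),
              sum(is.na(labs))))
  invisible(x)
}

#' Gold labels of a corpus
#'
#' @param corpus A [chart_corpus()].
#' @return Named integer vector of gold labels keyed by patient id.
#' @export
corpus_gold_labels <- function(corpus) {
  stats::setNames(
    vapply(corpus$charts, function(ch) ch$gold_label %||% NA_integer_,
           integer(1)),
    vapply(corpus$charts, `[[`, character(1), "patient_id"))
}

# ---- serialization ---------------------------------------------------------

note_to_list <- function(n) {
  list(note_id = n$note_id, note_type = n$note_type,
       timestamp = iso_datetime(n$timestamp), text = n$text,
       empty_flagged = n$empty_flagged)
}

note_from_list <- function(l) {
  clinical_note(l$note_id, l$note_type, l$timestamp, l$text,
                allow_empty = TRUE)
}

chart_to_list <- function(ch) {
  out <- list(
    patient_id = ch$patient_id,
    admission_date = iso_date(ch$admission_date),
    discharge_date = iso_date(ch$discharge_date),
    gold_label = ch$gold_label,
    age = ch$age, sex = ch$sex,
    died_in_hospital = ch$died_in_hospital,
    n_comorbidities = ch$n_comorbidities,
    notes = lapply(ch$notes, note_to_list))
  if (!is.null(ch$discharge_summary)) {
    out$discharge_summary <- note_to_list(ch$discharge_summary)
  }
  if (!is.null(ch$diagnosis_codes)) {
    out$diagnosis_codes <- lapply(seq_len(nrow(ch$diagnosis_codes)), function(i) {
      list(code = ch$diagnosis_codes$code[i],
           present_on_admission = ch$diagnosis_codes$present_on_admission[i])
    })
  }
  out
}

chart_from_list <- function(l) {
  dx <- NULL
  if (!is.null(l$diagnosis_codes)) {
    dx <- diagnosis_codes(
      vapply(l$diagnosis_codes, `[[`, character(1), "code"),
      vapply(l$diagnosis_codes, `[[`, logical(1), "present_on_admission"))
  }
  patient_chart(
    patient_id = l$patient_id,
    admission_date = l$admission_date,
    discharge_date = l$discharge_date,
    notes = lapply(l$notes, note_from_list),
    discharge_summary = if (!is.null(l$discharge_summary))
      note_from_list(l$discharge_summary),
    diagnosis_codes = dx,
    gold_label = if (is.null(l$gold_label)) NA_integer_ else l$gold_label,
    age = l$age %||% NA_integer_,
    sex = l$sex %||% NA_character_,
    died_in_hospital = l$died_in_hospital %||% NA,
    n_comorbidities = l$n_comorbidities %||% NA_integer_)
}

#' Write a corpus to a JSON-lines file
#'
#' Line 1 is a header object carrying `schema_version` and provenance; each
#' subsequent line is one chart. The field order is fixed, so writing the
#' same corpus twice yields byte-identical files (diffable, streamable).
#'
#' @param corpus A [chart_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "chart_corpus"))
  header <- c(list(kind = "peaescreen_corpus"), corpus$metadata)
  lines <- c(
    as.character(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA)),
    vapply(corpus$charts, function(ch) {
      as.character(jsonlite::toJSON(chart_to_list(ch), auto_unbox = TRUE,
                                    null = "null", na = "null", digits = NA))
    }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a JSON-lines file
#'
#' Charts failing schema validation are reported with their line numbers; in
#' the default lenient mode they are dropped with a warning, in strict mode
#' the first failure is fatal. A duplicate `patient_id` is always fatal
#' (a corpus holds one admission per patient).
#'
#' @param path Path written by [write_corpus()].
#' @param strict Abort on the first malformed line instead of skipping it.
#' @return A [chart_corpus()].
#' @export
read_corpus <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(chart_corpus(list(), source = path))
  header <- tryCatch(jsonlite::fromJSON(lines[[1]], simplifyVector = FALSE),
                     error = function(e) NULL)
  meta <- list(source = path, seed = NA)
  body <- lines
  if (!is.null(header) && identical(header$kind, "peaescreen_corpus")) {
    meta$source <- header$source %||% path
    meta$seed <- header$seed %||% NA
    body <- lines[-1]
  }
  charts <- list()
  bad <- character(0)
  for (i in seq_along(body)) {
    ch <- tryCatch(
      chart_from_list(jsonlite::fromJSON(body[[i]], simplifyVector = FALSE)),
      error = function(e) e)
    if (inherits(ch, "error")) {
      msg <- sprintf("line %d: %s", i + (length(body) < length(lines)),
                     conditionMessage(ch))
      if (strict) stop("malformed chart record at ", msg)
      bad <- c(bad, msg)
    } else {
      charts[[length(charts) + 1L]] <- ch
    }
  }
  if (length(bad)) {
    warning("skipped ", length(bad), " malformed chart record(s):\n  ",
            paste(bad, collapse = "\n  "))
  }
  ids <- vapply(charts, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  corpus <- chart_corpus(charts, source = meta$source, seed = meta$seed)
  corpus
}

#' Validate a patient chart
#'
#' Total over arbitrary field contents: violations are returned as data,
#' never raised. Cohorts built for PEAE screening conventionally exclude
#' admissions without a documented discharge summary; set
#' `require_discharge_summary` to surface that as a violation.
#'
#' @param chart A [patient_chart()] (or any list-alike with its fields).
#' @param require_discharge_summary Flag the absence of a discharge summary.
#' @return Character vector of violation codes (empty if the chart is valid).
#'   Codes: `date_order`, `missing_discharge_summary`, `empty_note_text`,
#'   `note_timestamp_out_of_range`, `notes_unsorted`, `missing_patient_id`.
#' @export
validate_chart <- function(chart, require_discharge_summary = FALSE) {
  v <- character(0)
  pid <- tryCatch(chart$patient_id, error = function(e) NULL)
  if (is.null(pid) || length(pid) != 1L || is.na(pid) || !nzchar(pid)) {
    v <- c(v, "missing_patient_id")
  }
  safe_date <- function(x) {
    d <- tryCatch(as.Date(x), error = function(e) as.Date(NA))
    if (length(d) != 1L) as.Date(NA) else d
  }
  adm <- safe_date(chart$admission_date)
  dis <- safe_date(chart$discharge_date)
  if (!is.na(adm) && !is.na(dis) && adm > dis) v <- c(v, "date_order")
  if (require_discharge_summary && is.null(chart$discharge_summary)) {
    v <- c(v, "missing_discharge_summary")
  }
  notes <- chart$notes
  if (is.list(notes) && length(notes)) {
    ts <- vapply(notes, function(n) {
      t <- tryCatch(as.numeric(n$timestamp), error = function(e) NA_real_)
      if (length(t) != 1L) NA_real_ else t
    }, numeric(1))
    if (!anyNA(ts) && is.unsorted(ts)) v <- c(v, "notes_unsorted")
    if (!is.na(adm) && !is.na(dis) && !anyNA(ts)) {
      lo <- as.numeric(as.POSIXct(adm, tz = "UTC")) - 30 * 86400
      hi <- as.numeric(as.POSIXct(dis, tz = "UTC")) + 86400  # through discharge day
      if (any(ts < lo | ts > hi)) v <- c(v, "note_timestamp_out_of_range")
    }
    empties <- vapply(notes, function(n) {
      isTRUE(tryCatch(!nzchar(n$text) && !isTRUE(n$empty_flagged),
                      error = function(e) TRUE))
    }, logical(1))
    if (any(empties)) v <- c(v, "empty_note_text")
  }
  v
}

#' Write detection predictions to a tab-separated table
#'
#' @param predictions Data frame with at least `patient_id` and `label`;
#'   `backend` and `config_tag` columns are added if missing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("patient_id", "label") %in% names(predictions)))
  if (is.null(predictions$backend)) predictions$backend <- NA_character_
  if (is.null(predictions$config_tag)) predictions$config_tag <- NA_character_
  utils::write.table(
    predictions[, c("patient_id", "label", "backend", "config_tag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#'
#' @param path Input path.
#' @return Data frame with columns `patient_id`, `label`, `backend`,
#'   `config_tag`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character"))
}
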