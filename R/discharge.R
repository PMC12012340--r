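# Discharge information extraction: instruct a generation backend to parse a
# discharge summary into six named clinical sections, then parse its
# structured output robustly.

DISCHARGE_SECTION_KEYS <- c(
  reason_for_hospitalization = "reason for hospitalization",
  significant_findings = "significant findings for the current admission",
  procedures_and_treatments = "procedures and treatments provided",
  medical_history = "medical history",
  discharge_condition = "discharge condition",
  patient_family_instructions = "patient and family instructions")

#' The six discharge-summary sections
#'
#' @return Named character vector mapping field names to the section names
#'   used in prompts.
#' @export
discharge_section_keys <- function() DISCHARGE_SECTION_KEYS

#' Construct a discharge-information record
#'
#' @param fields Named list with any subset of the six section fields (see
#'   [discharge_section_keys()]); missing sections are filled with `""`.
#' @param parsed_keys Which of the six were actually recovered; determines
#'   `status`: `ok` (all six), `partial` (some), `failed` (none).
#' @param diagnostic Optional free-text note on parse/backend trouble.
#' @return An object of class `discharge_info`.
#' @export
discharge_info <- function(fields = list(), parsed_keys = character(0),
                           diagnostic = NA_character_) {
  canon <- names(DISCHARGE_SECTION_KEYS)
  out <- stats::setNames(as.list(rep("", length(canon))), canon)
  for (k in intersect(names(fields), canon)) {
    out[[k]] <- as.character(fields[[k]] %||% "")
  }
  n <- length(intersect(parsed_keys, canon))
  status <- if (n == length(canon)) "ok" else if (n >= 1L) "partial" else "failed"
  structure(c(out, list(status = status,
                        parsed_keys = intersect(parsed_keys, canon),
                        diagnostic = diagnostic)),
            class = "discharge_info")
}

#' Build the discharge-summary extraction prompt
#'
#' Embeds the summary, enumerates the six target sections, and instructs the
#' backend to return a structured JSON object; the model dialect's wrapping
#' is applied last.
#'
#' @param summary_text Non-empty discharge summary text.
#' @param dialect A [prompt_dialect()] or dialect name.
#' @return The wrapped prompt string.
#' @export
build_discharge_prompt <- function(summary_text, dialect = "plain") {
  stopifnot(is.character(summary_text), length(summary_text) == 1L)
  if (!nzchar(trimws(summary_text))) {
    stop("build_discharge_prompt: empty summary text")
  }
  keys <- unname(DISCHARGE_SECTION_KEYS)
  payload <- paste0(
    "You are reviewing a hospital discharge summary. Extract the following ",
    "six sections: ", paste(keys, collapse = ", "), ".\n",
    "Return the result as a structured JSON object whose keys are exactly:\n",
    paste(sprintf("- \"%s\"", keys), collapse = "\n"), "\n",
    "Use an empty string for any section that is absent.\n\n",
    "--- DISCHARGE SUMMARY ---\n", summary_text,
    "\n--- END DISCHARGE SUMMARY ---\n")
  wrap_dialect(payload, dialect)
}

# normalize a key for tolerant matching: lowercase, non-alphanumerics to
# single spaces, trailing colons already eaten by the substitution
normalize_key <- function(k) {
  k <- tolower(k)
  k <- gsub("[^a-z0-9]+", " ", k)
  trimws(k)
}

match_section_key <- function(raw_key) {
  nk <- normalize_key(raw_key)
  if (!nzchar(nk)) return(NA_character_)
  pats <- c(reason_for_hospitalization = "reason",
            significant_findings = "significant|finding",
            procedures_and_treatments = "procedure|treatment",
            medical_history = "history",
            discharge_condition = "condition",
            patient_family_instructions = "instruction")
  hit <- names(pats)[vapply(pats, function(p) grepl(p, nk), logical(1))]
  if (length(hit) == 1L) hit else if (length(hit) > 1L) hit[1] else NA_character_
}

# first balanced {...} block in text, or NULL; brace counting ignores braces
# inside double-quoted strings
first_json_block <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; start <- NA_integer_; in_str <- FALSE; esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == "\"") in_str <- FALSE
      next
    }
    if (ch == "\"" && depth > 0L) { in_str <- TRUE; next }
    if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) return(substr(text, start, i))
      }
    }
  }
  NULL
}

#' Parse a generated discharge-extraction response
#'
#' Total over arbitrary text: locates the first structured block (tolerating
#' code fences and leading prose), matches keys case- and
#' punctuation-insensitively against the six section names, fills missing
#' sections with empty strings, and sets `status` accordingly. Unparseable
#' input yields `status = "failed"`, never an error. When JSON parsing fails,
#' a `key: value` line format is accepted as a fallback.
#'
#' @param raw Generated text.
#' @return A [discharge_info()].
#' @export
parse_discharge_response <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    return(discharge_info(diagnostic = "empty response"))
  }
  defenced <- gsub("```[a-zA-Z]*", "", raw)
  block <- first_json_block(defenced)
  vals <- NULL
  if (!is.null(block)) {
    vals <- tryCatch(jsonlite::fromJSON(block, simplifyVector = FALSE),
                     error = function(e) NULL)
    if (!is.null(vals) && (!is.list(vals) || is.null(names(vals)))) vals <- NULL
  }
  if (is.null(vals)) {
    # fallback: "Key: value" lines
    lines <- strsplit(defenced, "\n", fixed = TRUE)[[1]]
    m <- regmatches(lines,
                    regexec("^\\s*[\"'*-]*\\s*([A-Za-z][A-Za-z ._-]{2,60})[\"']?\\s*:\\s*(.*)$",
                            lines))
    kv <- Filter(function(x) length(x) == 3L, m)
    if (length(kv)) {
      vals <- stats::setNames(lapply(kv, function(x) trimws(x[3])),
                              vapply(kv, `[`, character(1), 2))
    }
  }
  if (is.null(vals) || !length(vals)) {
    return(discharge_info(diagnostic = "no structured block found"))
  }
  fields <- list(); parsed <- character(0)
  for (i in seq_along(vals)) {
    canon <- match_section_key(names(vals)[i])
    if (is.na(canon) || canon %in% parsed) next
    v <- vals[[i]]
    v <- if (is.null(v)) "" else paste(as.character(unlist(v)), collapse = " ")
    fields[[canon]] <- v
    parsed <- c(parsed, canon)
  }
  discharge_info(fields, parsed_keys = parsed)
}

#' Extract discharge information for one chart
#'
#' Composes [build_discharge_prompt()], the backend's generation, and
#' [parse_discharge_response()]. A backend failure yields
#' `status = "failed"` with the error message as diagnostic rather than an
#' exception, so a corpus run is never aborted by one chart.
#'
#' @param chart A [patient_chart()] with a discharge summary.
#' @param backend A [generation_backend()].
#' @param dialect A [prompt_dialect()] or dialect name.
#' @return A [discharge_info()] with attribute `patient_id`.
#' @export
extract_discharge_info <- function(chart, backend, dialect = "plain") {
  stopifnot(inherits(chart, "patient_chart"))
  if (is.null(chart$discharge_summary)) {
    stop("missing_discharge_summary: chart ", chart$patient_id,
         " has no discharge summary")
  }
  prompt <- build_discharge_prompt(chart$discharge_summary$text, dialect)
  raw <- tryCatch(backend$generate(prompt), error = function(e) e)
  info <- if (inherits(raw, "error")) {
    discharge_info(diagnostic = paste("backend failure:", conditionMessage(raw)))
  } else {
    parse_discharge_response(raw)
  }
  attr(info, "patient_id") <- chart$patient_id
  info
}

#' Serialize discharge information records
#'
#' Writes one JSON file per patient under `dir` (standardised per-patient
#' input artifacts for the detection stage) plus an aggregate JSON-lines
#' file.
#'
#' @param infos List of [discharge_info()] objects with `patient_id`
#'   attributes.
#' @param dir Output directory (created if needed).
#' @param aggregate Path of the aggregate JSON-lines file (default
#'   `discharge_info.jsonl` inside `dir`).
#' @return Invisibly, the aggregate path.
#' @export
write_discharge_info <- function(infos, dir,
                                 aggregate = file.path(dir, "discharge_info.jsonl")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(infos, function(info) {
    pid <- attr(info, "patient_id") %||% NA_character_
    rec <- c(list(patient_id = pid), unclass(info)[names(DISCHARGE_SECTION_KEYS)],
             list(status = info$status))
    j <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                       na = "null", digits = NA))
    writeLines(j, file.path(dir, paste0(pid, ".json")), useBytes = TRUE)
    j
  }, character(1))
  con <- file(aggregate, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(aggregate)
}
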