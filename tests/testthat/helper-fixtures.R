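# Shared fixtures: tiny charts and hand-controlled backends, built in code.

fix_note <- function(text, id = "n1", type = "progress note",
                     ts = "2020-05-03T10:00:00") {
  clinical_note(id, type, ts, text)
}

fix_chart <- function(patient_id = "P1", notes = list(fix_note("Stable.")),
                      admission = "2020-05-01", discharge = "2020-05-10",
                      summary = NULL, gold = NA_integer_, dx = NULL, ...) {
  patient_chart(patient_id, admission, discharge, notes = notes,
                discharge_summary = summary, diagnosis_codes = dx,
                gold_label = gold, ...)
}

# chart with a planted hospital-acquired PE mention on a given stay day
fix_pe_chart <- function(patient_id = "P1", day = 5, gold = 1L,
                         sentence = "CTPA demonstrates acute pulmonary embolism in the right lower lobe.") {
  adm <- as.Date("2020-05-01")
  notes <- list(
    fix_note("Vital signs stable overnight.", "n1",
             ts = "2020-05-02T09:00:00"),
    clinical_note("n2", "diagnostic imaging report",
                  sprintf("%sT10:00:00", adm + day), sentence))
  fix_chart(patient_id, notes, admission = adm, discharge = adm + 9,
            gold = gold)
}

# embedding backend with a fixed lookup table (unknown texts -> ones)
fix_lookup_backend <- function(table, dim) {
  embedding_backend("lookup", dim, function(texts) {
    t(vapply(texts, function(x) {
      if (!is.null(table[[x]])) table[[x]] else rep(1, dim)
    }, numeric(dim)))
  })
}

# generation backend returning a constant string
fix_const_backend <- function(text) {
  generation_backend("const", "1", function(prompt) text)
}

# data frame of standalone chunks (for filter tests)
fix_chunks <- function(texts) {
  n <- length(texts)
  data.frame(patient_id = rep("P1", n), note_id = rep("n1", n),
             chunk_index = seq_len(n) - 1L, start = rep(0L, n),
             end = nchar(texts), text = texts, word_count = word_count_vec(texts),
             timestamp = rep(as.POSIXct("2020-05-03 10:00:00", tz = "UTC"), n),
             stringsAsFactors = FALSE)
}

word_count_vec <- function(texts) {
  vapply(strsplit(trimws(texts), "\\s+"),
         function(x) length(x[nzchar(x)]), integer(1))
}

clean_rates <- c(negated_pe = 0, historical_pe = 0, poa_pe = 0,
                 pulmonary_edema = 0, prophylaxis_mention = 0)
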