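test_that("dialect wrapping never alters the user payload", {
  payload <- "Line one.\nLine [two] with <tags> and \"quotes\"."
  for (d in c("plain", "llama3", "mistral", "gemma", "phi3")) {
    wrapped <- wrap_dialect(payload, d)
    expect_identical(unwrap_dialect(wrapped, d), payload)
    expect_true(grepl(payload, wrapped, fixed = TRUE))
  }
  expect_match(wrap_dialect("x", "phi3"), "<\\|im_start\\|>")
  expect_match(wrap_dialect("x", "mistral"), "[INST]", fixed = TRUE)
})

test_that("detection prompts order sections and honor the discharge flag", {
  ch <- fix_pe_chart("P1", day = 5)
  chunks <- extract_evidence(ch, "keyword")
  early <- fix_chunks("Earlier PE mention in consult")
  early$timestamp <- as.POSIXct("2020-05-03 08:00:00", tz = "UTC")
  both <- rbind(chunks, early)
  di <- parse_discharge_response(
    '{"reason for hospitalization": "pneumonia"}')
  bundle <- evidence_bundle("P1", both, di, "2020-05-01", "2020-05-10")
  expect_identical(bundle$chunks$text[1], "Earlier PE mention in consult")

  p <- build_detection_prompt(bundle, "phi3", include_discharge = TRUE)
  expect_match(p, "<\\|im_start\\|>")
  expect_match(p, "Admission date: 2020-05-01", fixed = TRUE)
  for (txt in both$text) expect_match(p, txt, fixed = TRUE)
  expect_lt(regexpr("Earlier PE mention", p),
            regexpr("demonstrates acute pulmonary", p))
  expect_match(p, "DISCHARGE INFORMATION")
  expect_match(p, "pneumonia")

  p_off <- build_detection_prompt(bundle, "phi3", include_discharge = FALSE)
  expect_false(grepl("DISCHARGE INFORMATION", p_off))

  none <- evidence_bundle("P1", fix_chunks(character(0)), NULL,
                          "2020-05-01", "2020-05-10")
  expect_match(build_detection_prompt(none, "plain"),
               "No PE-related text was retrieved", fixed = TRUE)
})

test_that("the evidence budget drops oldest lines first and logs it", {
  texts <- sprintf("PE evidence item %02d with some padding words", 1:6)
  chunks <- fix_chunks(texts)
  chunks$timestamp <- as.POSIXct("2020-05-02", tz = "UTC") + (1:6) * 86400
  bundle <- evidence_bundle("P1", chunks, NULL, "2020-05-01", "2020-05-10")
  p <- build_detection_prompt(bundle, "plain", max_chars = 200)
  expect_false(grepl("item 01", p))
  expect_true(grepl("item 06", p))
  expect_gt(attr(p, "truncated"), 0L)
})

test_that("first-sentence yes/no classification follows the stated rule", {
  r1 <- classify_response("Yes. The CTPA on day 5 confirms a new PE.")
  expect_identical(r1$label, 1L)
  expect_identical(r1$justification, "The CTPA on day 5 confirms a new PE.")

  r2 <- classify_response("No, PE was present on admission.")
  expect_identical(r2$label, 0L)

  r3 <- classify_response("The answer is yes")
  expect_identical(r3$label, 1L)
  expect_identical(r3$justification, "")

  r4 <- classify_response("")
  expect_identical(r4$label, 0L)
  expect_true(r4$flagged)

  # word-boundary: "yesterday" is not an answer; later sentences don't count
  expect_identical(classify_response("Yesterday was fine.")$label, 0L)
  expect_identical(classify_response("Unclear. Yes though.")$label, 0L)
  expect_identical(classify_response("YES!\nDefinitely.")$label, 1L)

  # purity
  expect_identical(classify_response("Yes. x"), classify_response("Yes. x"))
})

test_that("the mock backend applies negation, temporal and assertion rules", {
  mk_prompt <- function(sentence, day) {
    ts <- as.POSIXct("2020-05-01", tz = "UTC") + day * 86400 + 10 * 3600
    ck <- fix_chunks(sentence)
    ck$timestamp <- ts
    build_detection_prompt(
      evidence_bundle("P1", ck, NULL, "2020-05-01", "2020-05-20"), "plain")
  }
  be <- mock_generation_backend()
  expect_match(be$generate(mk_prompt(
    "CTPA demonstrates acute pulmonary embolism.", 6)), "^Yes")
  expect_match(be$generate(mk_prompt(
    "CTPA shows no evidence of pulmonary embolism.", 6)), "^No")
  expect_match(be$generate(mk_prompt(
    "History of pulmonary embolism noted in 2015.", 6)), "^No")
  # present on admission: affirming text but dated day 0
  expect_match(be$generate(mk_prompt(
    "CTPA demonstrates acute pulmonary embolism.", 0)), "^No")
  # mention without an assertion verb is not an affirmation
  expect_match(be$generate(mk_prompt("Questionable PE.", 6)), "^No")
})

test_that("per-chart detection reproduces planted gold labels", {
  cfg <- detection_config()
  be <- mock_generation_backend()
  pos <- detect_peae(fix_pe_chart("P1", day = 5, gold = 1L), cfg, be)
  expect_identical(pos$label, 1L)
  expect_match(pos$raw_response, "^Yes")
  expect_match(pos$prompt_hash, "^[0-9a-f]{8}$")

  poa <- detect_peae(fix_pe_chart("P2", day = 0, gold = 0L), cfg, be)
  expect_identical(poa$label, 0L)

  empty <- fix_chart("P3", notes = list())
  expect_error(detect_peae(empty, cfg, be), "no notes")
})

test_that("backend failures abort by default and are recorded when lenient", {
  boom <- generation_backend("boom", "1", function(p) stop("down"))
  ch <- fix_pe_chart("P1")
  expect_error(detect_peae(ch, detection_config(), boom), "down")
  r <- detect_peae(ch, detection_config(lenient = TRUE), boom)
  expect_identical(r$label, 0L)
  expect_true(r$flagged)
})

test_that("clean synthetic corpora are recovered exactly end-to-end", {
  g <- generate_corpus(generator_config(n_patients = 250, prevalence = 0.06,
                                        seed = 31,
                                        confounder_rates = clean_rates))
  for (method in c("keyword", "semantic")) {
    preds <- detect_corpus(g$corpus, detection_config(method = method),
                           mock_generation_backend())
    expect_identical(preds$label, preds$gold)
  }
})

test_that("with confounders on, every false positive carries a confounder tag", {
  g <- generate_corpus(generator_config(
    n_patients = 400, prevalence = 0.05, seed = 33,
    confounder_rates = c(negated_pe = 0.05, historical_pe = 0.05,
                         poa_pe = 0.05, pulmonary_edema = 0.05,
                         prophylaxis_mention = 0.05)))
  preds <- detect_corpus(g$corpus, detection_config(),
                         mock_generation_backend())
  expect_identical(preds$label[preds$gold == 1L],
                   preds$gold[preds$gold == 1L])   # sensitivity intact
  fp <- preds$patient_id[preds$label == 1L & preds$gold == 0L]
  expect_gt(length(fp), 0L)
  expect_true(all(has_confounder(g$annotations)[fp]))
})
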