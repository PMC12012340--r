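test_that("chunking splits notes at the requested granularity with exact spans", {
  blank <- clinical_note("n0", "progress note", "2020-05-03T10:00:00", "",
                         allow_empty = TRUE)
  expect_identical(nrow(chunk_note(blank, patient_id = "P1")), 0L)

  # 250-word note under a 100-word window: 100/100/50 with contiguous spans
  n250 <- fix_note(paste(rep("word", 250), collapse = " "))
  ck <- chunk_note(n250, "word_window", max_words = 100, overlap = 0,
                   patient_id = "P1")
  expect_identical(ck$word_count, c(100L, 100L, 50L))
  expect_identical(ck$start[1], 0L)
  expect_identical(ck$start[-1], ck$end[-3])
  expect_identical(ck$end[3], nchar(n250$text))

  # paragraph strategy: chunk texts equal the paragraphs
  n2p <- fix_note("First paragraph here.\n\nSecond paragraph there.")
  ck2 <- chunk_note(n2p, "paragraph", patient_id = "P1")
  expect_identical(ck2$text, c("First paragraph here.",
                               "Second paragraph there."))

  # sentence strategy keeps terminators with the sentence
  cks <- chunk_note(fix_note("One done. Two done! Three"), "sentence")
  expect_length(cks$text, 3L)
  expect_match(cks$text[1], "^One done\\.")
})

test_that("chunk text always equals the note substring at its span", {
  set.seed(41)
  words <- c("alpha", "beta", "gamma", "delta.", "eps!", "zeta")
  for (i in 1:20) {
    body <- paste(sample(words, sample(5:60, 1), replace = TRUE),
                  collapse = " ")
    if (i %% 3 == 0) body <- sub(" ", "\n\n", body)
    note <- fix_note(body)
    for (strat in c("paragraph", "sentence", "word_window")) {
      ck <- chunk_note(note, strat, max_words = 10,
                       overlap = if (strat == "word_window") 3 else 0,
                       patient_id = "P1")
      expect_identical(ck$text,
                       substring(note$text, ck$start + 1L, ck$end))
      expect_true(all(ck$word_count >= 1L))
      expect_true(all(ck$word_count <= 10L))
    }
  }
})

test_that("oversized paragraphs fall back to the word-window budget", {
  long <- fix_note(paste0("Intro.\n\n",
                          paste(rep("w", 300), collapse = " ")))
  ck <- chunk_note(long, "paragraph", max_words = 128)
  expect_gt(nrow(ck), 2L)
  expect_true(all(ck$word_count <= 128L))
})

test_that("keyword filter honors case and word-boundary semantics", {
  texts <- c("CT chest showed acute PE in the right lower lobe",
             "the patient remains hoPEful about discharge",
             "pulmonary edema improving on diuresis",
             "known thrombosis of the portal vein",
             "ctpe was performed this morning",
             "routine physiotherapy session")
  kept <- keyword_filter(fix_chunks(texts))
  expect_identical(kept$text, texts[c(1, 4, 5)])
  expect_identical(keyword_filter(fix_chunks(character(0)))$text,
                   character(0))
  # idempotence and provenance preservation
  expect_identical(keyword_filter(kept), kept)
  expect_identical(kept$chunk_index, c(0L, 3L, 4L))
})

test_that("keyword filter matches an independent regex-scan oracle", {
  set.seed(7)
  vocab <- c("PE", "pe", "hoPEful", "ctpe", "thrombosis", "edema",
             "pulmonary", "embolism", "clot", "blood", "stable", "ropey")
  spec <- keyword_spec()
  oracle <- function(text) {
    pats <- c("(?<![A-Za-z0-9_])PE(?![A-Za-z0-9_])")
    ins <- c("blood clot", "thrombosis", "pulmonary embolism",
             "pulmonary embolus", "ctpe", "pe")
    hit <- grepl(pats, text, perl = TRUE)
    for (t in ins) {
      hit <- hit || grepl(paste0("(?i)(?<![A-Za-z0-9_])", t,
                                 "(?![A-Za-z0-9_])"), text, perl = TRUE)
    }
    hit
  }
  for (i in 1:50) {
    text <- paste(sample(vocab, sample(3:12, 1), replace = TRUE),
                  collapse = " ")
    expect_identical(has_keyword(text, spec), oracle(text), label = text)
  }
})

test_that("cosine similarity matches hand computation and rejects zero vectors", {
  expect_equal(cosine_similarity(c(3, 1, 2), c(3, 1, 2)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("semantic filter keeps ceil(n%) top chunks in document order", {
  texts <- sprintf("chunk number %d", 1:10)
  chunks <- fix_chunks(texts)
  # backend scoring chunk i with similarity to single exemplar = i/10,
  # via 2-d vectors at controlled angles
  table <- stats::setNames(
    lapply(1:10, function(i) {
      a <- acos(i / 10); c(cos(a), sin(a))
    }), texts)
  table[["exemplar"]] <- c(1, 0)
  be <- fix_lookup_backend(table, 2)
  out <- semantic_filter(chunks, "exemplar", be,
                         semantic_filter_config(top_percent = 25))
  expect_identical(out$text, texts[8:10])          # ceil(2.5) = 3, top scores
  expect_identical(out$chunk_index, chunks$chunk_index[8:10])

  # top_percent = 100 returns everything in order
  all_out <- semantic_filter(chunks, "exemplar", be,
                             semantic_filter_config(top_percent = 100))
  expect_identical(all_out$text, texts)

  # a chunk identical to an exemplar is retained at a tight threshold
  mix <- fix_chunks(c("unrelated words entirely", "exemplar",
                      "other filler text"))
  tight <- semantic_filter(mix, "exemplar", be,
                           semantic_filter_config(top_percent = 34))
  expect_true("exemplar" %in% tight$text)
})

test_that("semantic filter agrees with a brute-force rank oracle", {
  set.seed(13)
  vocab <- c("pulmonary", "embolism", "ctpa", "edema", "stable", "walk",
             "clot", "scan", "note", "lobe", "acute", "daily")
  be <- hash_embedding_backend(64)
  ex <- c("ctpa shows acute pulmonary embolism", "new clot on scan")
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    texts <- vapply(seq_len(n), function(i) {
      paste(sample(vocab, sample(2:8, 1), replace = TRUE), collapse = " ")
    }, character(1))
    chunks <- fix_chunks(texts)
    pct <- sample(c(5, 10, 25, 50, 90), 1)
    got <- semantic_filter(chunks, ex, be, semantic_filter_config(pct))
    # oracle: score everything, sort, take ceil, restore order
    emb <- embed_texts(be, texts); exe <- embed_texts(be, ex)
    sc <- apply(emb, 1, function(u) {
      max(apply(exe, 1, function(v) {
        if (sum(u^2) == 0) -Inf else cosine_similarity(u, v)
      }))
    })
    keep <- sort(order(-sc, seq_len(n))[seq_len(ceiling(pct / 100 * n))])
    expect_identical(got$text, texts[keep])
    expect_identical(nrow(got), as.integer(ceiling(pct / 100 * n)))
  }
})

test_that("extract_evidence runs chunking plus the chosen filter per chart", {
  pos <- fix_pe_chart("P1")
  hits <- extract_evidence(pos, "keyword")
  expect_true(any(grepl("pulmonary embolism", hits$text)))
  expect_identical(unique(hits$patient_id), "P1")

  none <- fix_chart(notes = list(fix_note("Vitals stable."),
                                 fix_note("Diet advanced.", id = "n2")))
  out <- extract_evidence(none, "keyword")
  expect_identical(nrow(out), 0L)
  expect_true(attr(out, "no_evidence"))

  sem <- extract_evidence(pos, "semantic",
                          config = semantic_filter_config(50))
  expect_true(any(grepl("pulmonary embolism", sem$text)))
})

test_that("negate_chunk applies the template deterministically", {
  expect_identical(negate_chunk("acute PE identified on CTPA"),
                   "No evidence of the following was found: acute PE identified on CTPA")
  expect_error(negate_chunk(""), "empty")
  twice <- negate_chunk(negate_chunk("x"))
  expect_identical(
    twice,
    "No evidence of the following was found: No evidence of the following was found: x")
})

test_that("triplet construction follows the anchor/positive/negative rules", {
  pos_chart <- fix_chart("POS", notes = list(
    fix_note("CTPA demonstrates acute PE today.\n\nNew pulmonary embolism confirmed.",
             "n1")), gold = 1L)
  neg_chart <- fix_chart("NEG", notes = list(
    fix_note("Vitals stable.\n\nAmbulating in hallway.", "n1")), gold = 0L)
  corp <- chart_corpus(list(pos_chart, neg_chart))

  tr0 <- build_triplets(corp, negated_fraction = 0, seed = 3)
  expect_identical(nrow(tr0), 2L)
  expect_true(all(tr0$negative_source == "non_pe_chart"))
  expect_true(all(has_keyword(tr0$anchor)))
  expect_false(any(has_keyword(tr0$negative)))
  expect_true(all(tr0$anchor != tr0$positive))

  tr1 <- build_triplets(corp, negated_fraction = 1, seed = 3)
  expect_identical(tr1$negative,
                   vapply(tr1$anchor, negate_chunk, character(1),
                          USE.NAMES = FALSE))

  # determinism under seed
  expect_identical(build_triplets(corp, negated_fraction = 0.5, seed = 11),
                   build_triplets(corp, negated_fraction = 0.5, seed = 11))

  # no keyword chunks -> empty; no negatives -> error
  blank <- chart_corpus(list(fix_chart("A", gold = 1L), neg_chart))
  expect_identical(nrow(build_triplets(blank)), 0L)
  no_neg <- chart_corpus(list(pos_chart))
  expect_error(build_triplets(no_neg, negated_fraction = 0), "negative")
})

test_that("triplet accuracy counts strict wins and treats ties as failures", {
  tr <- data.frame(anchor = c("a1", "a2", "a3", "a4"),
                   positive = c("p1", "p2", "p3", "p4"),
                   negative = c("n1", "n2", "n3", "n4"),
                   negative_source = "non_pe_chart",
                   stringsAsFactors = FALSE)
  # anchors identical to positives except a4, whose negative ties
  tab <- list(a1 = c(1, 0), p1 = c(1, 0), n1 = c(0, 1),
              a2 = c(0, 1), p2 = c(0, 1), n2 = c(1, 0),
              a3 = c(1, 1), p3 = c(1, 1), n3 = c(1, 0),
              a4 = c(1, 0), p4 = c(0, 1), n4 = c(0, 1))
  be <- fix_lookup_backend(tab, 2)
  expect_equal(triplet_accuracy(tr, be), 0.75)

  all_same <- fix_lookup_backend(list(), 2)   # everything embeds identically
  expect_equal(triplet_accuracy(tr[1, ], all_same), 0)
  expect_error(triplet_accuracy(tr[0, ], be), "empty")
})

test_that("reduction summaries use linear-interpolation quartiles", {
  s3 <- data.frame(patient_id = c("a", "b", "c"), n_chunks = c(1L, 2L, 3L),
                   n_words = c(10L, 20L, 30L))
  out <- summarize_reduction(list(raw = s3))
  expect_equal(out$chunks_median, 2)
  expect_equal(out$total_chunks, 6L)

  s1 <- data.frame(patient_id = "a", n_chunks = 5L, n_words = 50L)
  out1 <- summarize_reduction(list(raw = s1))
  expect_equal(out1$chunks_median, 5)
  expect_equal(out1$chunks_q3 - out1$chunks_q1, 0)

  s4 <- data.frame(patient_id = letters[1:4], n_chunks = 1:4,
                   n_words = c(5L, 6L, 7L, 8L))
  out4 <- summarize_reduction(list(raw = s4))
  expect_equal(out4$chunks_median, 2.5)
  expect_equal(out4$chunks_q1, 1.75)
  expect_equal(out4$chunks_q3, 3.25)

  other <- data.frame(patient_id = c("a", "b"), n_chunks = 1L, n_words = 1L)
  expect_error(summarize_reduction(list(raw = s3, filtered = other)),
               "patient sets")
})
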