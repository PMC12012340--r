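# Evidence extraction: reduce a chart's notes to a handful of chunks likely
# to bear on pulmonary embolism, by chunking plus keyword or
# embedding-similarity filtering.

empty_chunks <- function() {
  data.frame(patient_id = character(0), note_id = character(0),
             chunk_index = integer(0), start = integer(0), end = integer(0),
             text = character(0), word_count = integer(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Build the chunk rows for one note given 0-based half-open span boundaries.
chunks_from_spans <- function(note, patient_id, starts, ends) {
  txt <- substring(note$text, starts + 1L, ends)
  keep <- grepl("\\S", txt)
  txt <- txt[keep]; starts <- starts[keep]; ends <- ends[keep]
  if (!length(txt)) return(empty_chunks())
  data.frame(patient_id = rep(as.character(patient_id), length(txt)),
             note_id = rep(note$note_id, length(txt)),
             chunk_index = seq_along(txt) - 1L,
             start = as.integer(starts), end = as.integer(ends),
             text = txt, word_count = word_count(txt),
             timestamp = rep(note$timestamp, length(txt)),
             stringsAsFactors = FALSE)
}

# Word-window span boundaries over a substring [off, off+nchar) of the note.
word_window_spans <- function(text, off, max_words, overlap) {
  toks <- ws_tokens(text)
  n <- nrow(toks)
  if (n == 0L) return(NULL)
  step <- max_words - overlap
  firsts <- seq(1L, n, by = step)
  # drop trailing windows fully contained in the previous one
  firsts <- firsts[firsts == 1L | firsts + max_words - 1L <= n + step - 1L]
  if (overlap == 0L) {
    # contiguous spans: each window runs to the start of the next window's
    # first word, so the spans tile the text exactly
    starts <- c(0L, toks$start[firsts[-1]] - 1L)
    ends <- c(starts[-1], nchar(text))
  } else {
    lasts <- pmin(firsts + max_words - 1L, n)
    keep <- !duplicated(lasts)   # collapse identical trailing windows
    firsts <- firsts[keep]; lasts <- lasts[keep]
    starts <- toks$start[firsts] - 1L
    ends <- toks$end[lasts]
  }
  cbind(start = starts + off, end = ends + off)
}

#' Split a clinical note into chunks
#'
#' Divides a note into retrieval units at one of three granularities:
#' paragraphs (blank-line separated), sentences, or fixed-size word windows.
#' A paragraph or sentence exceeding `max_words` is re-split by the
#' word-window rule so no chunk exceeds the budget. Character spans are
#' 0-based half-open into the note text, and each chunk's `text` equals the
#' note substring at its span; with `overlap = 0` the word-window spans tile
#' the note exactly.
#'
#' @param note A [clinical_note()].
#' @param strategy `"paragraph"` (default), `"sentence"`, or `"word_window"`.
#' @param max_words Word budget per chunk (whitespace tokens); default 128.
#' @param overlap Words shared by consecutive word windows; must be smaller
#'   than `max_words`.
#' @param patient_id Provenance id stamped on each chunk.
#' @return A data frame of chunks (possibly zero rows for an empty note)
#'   with columns `patient_id`, `note_id`, `chunk_index`, `start`, `end`,
#'   `text`, `word_count`, `timestamp`.
#' @export
#' @examples
#' n <- clinical_note("n1", "progress", "2020-01-02T08:00:00",
#'                    "Stable overnight.\n\nCTPA demonstrates acute PE.")
#' chunk_note(n, "paragraph")$text
chunk_note <- function(note, strategy = c("paragraph", "sentence",
                                          "word_window"),
                       max_words = 128L, overlap = 0L, patient_id = NA) {
  strategy <- match.arg(strategy)
  stopifnot(max_words >= 1L, overlap >= 0L, overlap < max_words)
  text <- note$text
  if (!nzchar(text)) return(empty_chunks())

  if (strategy == "word_window") {
    sp <- word_window_spans(text, 0L, max_words, overlap)
    if (is.null(sp)) return(empty_chunks())
    return(chunks_from_spans(note, patient_id, sp[, "start"], sp[, "end"]))
  }

  if (strategy == "paragraph") {
    seps <- gregexpr("\\n[ \t]*\\n+", text)[[1]]
    if (seps[1] == -1L) {
      starts <- 0L; ends <- nchar(text)
    } else {
      slen <- attr(seps, "match.length")
      starts <- c(0L, as.integer(seps) + slen - 1L)
      ends <- c(as.integer(seps) - 1L, nchar(text))
    }
  } else { # sentence: break after terminator runs or newlines
    b <- gregexpr("[.!?]+(\\s+|$)|\\n+", text)[[1]]
    if (b[1] == -1L) {
      starts <- 0L; ends <- nchar(text)
    } else {
      blen <- attr(b, "match.length")
      cut <- as.integer(b) + blen - 1L
      cut <- cut[cut < nchar(text)]
      starts <- c(0L, cut)
      ends <- c(cut, nchar(text))
    }
  }

  # enforce the word budget: oversize segments fall back to word windows
  pieces <- mapply(function(s, e) {
    seg <- substring(text, s + 1L, e)
    if (word_count(seg) > max_words) {
      word_window_spans(seg, s, max_words, overlap)
    } else {
      cbind(start = s, end = e)
    }
  }, starts, ends, SIMPLIFY = FALSE)
  sp <- do.call(rbind, pieces)
  chunks_from_spans(note, patient_id, sp[, "start"], sp[, "end"])
}

# ---- keyword filter --------------------------------------------------------

#' Keyword specification for PE-relevant chunk retrieval
#'
#' Terms whose presence marks a chunk as potentially PE-relevant. Short
#' abbreviations ("PE") are matched case-sensitively at word boundaries so
#' that e.g. "hoPEful" or "peak" never hit, while multiword terms and the
#' lowercase variants are matched case-insensitively. The printed defaults
#' are a starting set, not a closed vocabulary: pass your own lists to match
#' local documentation habits.
#'
#' @param exact_terms Case-sensitive tokens (default `"PE"`).
#' @param insensitive_terms Case-insensitive terms/phrases.
#' @param word_boundary Require word-boundary matches (default `TRUE`).
#' @return An object of class `keyword_spec`.
#' @export
keyword_spec <- function(exact_terms = c("PE"),
                         insensitive_terms = c("blood clot", "thrombosis",
                                               "pulmonary embolism",
                                               "pulmonary embolus",
                                               "ctpe", "pe"),
                         word_boundary = TRUE) {
  terms <- c(exact_terms, insensitive_terms)
  if (any(!nzchar(trimws(terms)))) stop("keyword_spec: empty term")
  structure(list(exact_terms = exact_terms,
                 insensitive_terms = insensitive_terms,
                 word_boundary = isTRUE(word_boundary)),
            class = "keyword_spec")
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

term_pattern <- function(term, word_boundary) {
  p <- regex_escape(term)
  if (word_boundary) p <- paste0("\\b", p, "\\b") else p
}

#' Test texts for PE keywords
#'
#' @param texts Character vector.
#' @param spec A [keyword_spec()].
#' @return Logical vector: does each text contain at least one keyword?
#' @export
has_keyword <- function(texts, spec = keyword_spec()) {
  stopifnot(inherits(spec, "keyword_spec"))
  hit <- rep(FALSE, length(texts))
  for (t in spec$exact_terms) {
    hit <- hit | grepl(term_pattern(t, spec$word_boundary), texts, perl = TRUE)
  }
  for (t in spec$insensitive_terms) {
    hit <- hit | grepl(term_pattern(t, spec$word_boundary), texts,
                       perl = TRUE, ignore.case = TRUE)
  }
  hit
}

#' Keyword-based chunk filter
#'
#' Retains exactly the chunks containing at least one keyword under the
#' spec's matching semantics, in their original order; chunks are never
#' added or mutated, so filtering is idempotent and provenance-preserving.
#'
#' @param chunks Chunk data frame from [chunk_note()].
#' @param spec A [keyword_spec()].
#' @return The retained subset of `chunks`.
#' @export
keyword_filter <- function(chunks, spec = keyword_spec()) {
  if (!nrow(chunks)) return(chunks)
  chunks[has_keyword(chunks$text, spec), , drop = FALSE]
}

# ---- embeddings & semantic filter ------------------------------------------

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("cosine_similarity: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine_similarity: zero vector")
  sum(u * v) / (nu * nv)
}

#' Construct an embedding backend
#'
#' An embedding backend maps a character vector to a numeric matrix with one
#' fixed-length row per input text, deterministically for a fixed backend
#' state. Any sentence-embedding model can be adapted to this contract; the
#' package ships [hash_embedding_backend()] as a dependency-free default.
#'
#' @param name Backend label (recorded in artifacts).
#' @param dim Embedding dimension.
#' @param embed `function(texts) -> matrix(length(texts), dim)`.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, dim, embed) {
  stopifnot(is.function(embed), dim >= 1L)
  structure(list(name = name, dim = as.integer(dim), embed = embed),
            class = "embedding_backend")
}

#' Embed texts through a backend, with validation
#'
#' @param backend An [embedding_backend()].
#' @param texts Character vector.
#' @return Numeric matrix, one row per text.
#' @export
embed_texts <- function(backend, texts) {
  stopifnot(inherits(backend, "embedding_backend"))
  m <- backend$embed(texts)
  if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != backend$dim ||
      !all(is.finite(m))) {
    stop("embedding backend '", backend$name,
         "' violated its contract (shape or non-finite values)")
  }
  m
}

# token -> (index, sign) under feature hashing; cached per session
.hash_tok_env <- new.env(parent = emptyenv())

hash_token <- function(tok, dim) {
  key <- paste0(dim, ":", tok)
  hit <- .hash_tok_env[[key]]
  if (!is.null(hit)) return(hit)
  h <- strtoi(substr(fnv1a_hex(tok), 1, 7), 16L)
  out <- c(idx = h %% dim + 1L, sgn = if (h %% 2L == 0L) 1L else -1L)
  assign(key, out, envir = .hash_tok_env)
  out
}

#' Feature-hashing bag-of-words embedding backend
#'
#' A lightweight lexical sentence embedder: texts are lowercased, tokenised
#' on non-alphanumerics, and each token is hashed to a signed coordinate of a
#' fixed-dimension vector (the hashing trick). Two texts sharing vocabulary
#' get high cosine similarity; disjoint vocabularies score near zero. It is
#' deterministic and fast, which makes it suitable as the default retrieval
#' backend and as the reference backend in tests; a trained neural sentence
#' embedder can be substituted through the [embedding_backend()] contract
#' when semantic (rather than lexical) similarity is needed.
#'
#' @param dim Embedding dimension (default 256).
#' @return An [embedding_backend()].
#' @export
hash_embedding_backend <- function(dim = 256L) {
  dim <- as.integer(dim)
  embed <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- strsplit(tolower(texts[i]), "[^a-z0-9]+")[[1]]
      toks <- toks[nzchar(toks)]
      for (tok in toks) {
        h <- hash_token(tok, dim)
        out[i, h[["idx"]]] <- out[i, h[["idx"]]] + h[["sgn"]]
      }
    }
    out
  }
  embedding_backend(sprintf("hash-bow-%d", dim), dim, embed)
}

#' Default exemplar sentences for semantic retrieval
#'
#' Ten authored sentences mimicking PE-affirming content across note genres
#' (imaging reports, nursing and assessment notes, discharge summaries).
#' They are configuration, not ground truth: replace them with exemplars
#' drawn from your own documentation style for best retrieval.
#'
#' @return Character vector of 10 exemplar sentences.
#' @export
example_sentences <- function() {
  c("CTPA demonstrates acute pulmonary embolism in the right lower lobe.",
    "CT chest confirmed a new PE with associated pulmonary infarct.",
    "Patient developed a pulmonary embolus on postoperative day three.",
    "Nursing note: patient acutely dyspneic and hypoxic, PE confirmed on imaging.",
    "Assessment: acute pulmonary embolism, therapeutic anticoagulation started.",
    "Hospital course complicated by pulmonary embolism requiring heparin infusion.",
    "VQ scan read as high probability for pulmonary embolism.",
    "New bilateral segmental pulmonary emboli identified on CT angiogram.",
    "Thrombosis extending into the pulmonary arteries diagnosed this admission.",
    "Sudden pleuritic chest pain; imaging positive for pulmonary embolism.")
}

#' Semantic filter configuration
#'
#' @param top_percent Retain the top `top_percent` of chunks by similarity;
#'   in `(0, 100]`. The default 5 gives an order-of-magnitude reduction after
#'   keywordless chunking on realistic note volumes.
#' @param aggregation How per-exemplar similarities combine into one chunk
#'   score; `"max"` (default: a chunk need resemble only one exemplar genre)
#'   or `"mean"`.
#' @return An object of class `semantic_filter_config`.
#' @export
semantic_filter_config <- function(top_percent = 5, aggregation = c("max", "mean")) {
  stopifnot(top_percent > 0, top_percent <= 100)
  structure(list(top_percent = top_percent,
                 aggregation = match.arg(aggregation)),
            class = "semantic_filter_config")
}

#' Semantic-similarity chunk filter
#'
#' Scores every chunk by the configured aggregation of its cosine
#' similarities to the exemplar sentences and retains the
#' `ceiling(top_percent/100 * n)` best, re-sorted into original document
#' order. Ties are broken in favour of the earlier document position. A
#' chunk whose embedding is all-zero (no recognisable tokens) scores
#' `-Inf` and is retained only if the quota forces it.
#'
#' @param chunks Chunk data frame.
#' @param examples Character vector of exemplar sentences
#'   (default [example_sentences()]).
#' @param backend An [embedding_backend()].
#' @param config A [semantic_filter_config()].
#' @return The retained subset of `chunks`, with a `score` column appended.
#' @export
semantic_filter <- function(chunks, examples = example_sentences(),
                            backend = hash_embedding_backend(),
                            config = semantic_filter_config()) {
  stopifnot(inherits(config, "semantic_filter_config"), length(examples) >= 1L)
  if (!nrow(chunks)) {
    out <- chunks; out$score <- numeric(0); return(out)
  }
  emb_ex <- embed_texts(backend, examples)
  emb_ch <- embed_texts(backend, chunks$text)
  norm_ex <- sqrt(rowSums(emb_ex^2))
  norm_ch <- sqrt(rowSums(emb_ch^2))
  if (any(norm_ex == 0)) stop("exemplar embedded to a zero vector")
  sims <- (emb_ch %*% t(emb_ex)) / outer(norm_ch, norm_ex)
  sims[norm_ch == 0, ] <- -Inf
  score <- if (config$aggregation == "max") {
    apply(sims, 1, max)
  } else {
    rowMeans(sims)
  }
  n_keep <- ceiling(config$top_percent / 100 * nrow(chunks))
  ord <- order(-score, seq_len(nrow(chunks)))   # ties -> earlier position
  keep <- sort(ord[seq_len(n_keep)])            # back to document order
  out <- chunks[keep, , drop = FALSE]
  out$score <- score[keep]
  out
}

#' Extract PE-relevant evidence chunks from one chart
#'
#' Chunks every clinical note of the chart (the discharge summary is
#' deliberately excluded — it is handled by the discharge-extraction module)
#' and applies the selected filter. An empty result is legal and carries the
#' attribute `no_evidence = TRUE` so downstream prompt construction can
#' insert its placeholder.
#'
#' @param chart A [patient_chart()].
#' @param method `"keyword"` or `"semantic"`.
#' @param spec [keyword_spec()] used when `method = "keyword"`.
#' @param strategy,max_words,overlap Chunking parameters (see [chunk_note()]).
#' @param examples,backend,config Semantic retrieval parameters (see
#'   [semantic_filter()]).
#' @return Chunk data frame with provenance columns intact.
#' @export
extract_evidence <- function(chart, method = c("keyword", "semantic"),
                             spec = keyword_spec(),
                             strategy = "paragraph", max_words = 128L,
                             overlap = 0L,
                             examples = example_sentences(),
                             backend = hash_embedding_backend(),
                             config = semantic_filter_config()) {
  method <- match.arg(method)
  stopifnot(inherits(chart, "patient_chart"))
  pieces <- lapply(chart$notes, chunk_note, strategy = strategy,
                   max_words = max_words, overlap = overlap,
                   patient_id = chart$patient_id)
  all_chunks <- if (length(pieces)) do.call(rbind, pieces) else empty_chunks()
  rownames(all_chunks) <- NULL
  out <- if (method == "keyword") {
    keyword_filter(all_chunks, spec)
  } else {
    semantic_filter(all_chunks, examples, backend, config)
  }
  attr(out, "n_raw_chunks") <- nrow(all_chunks)
  attr(out, "n_raw_words") <- sum(all_chunks$word_count)
  attr(out, "no_evidence") <- nrow(out) == 0L
  out
}

# ---- triplets --------------------------------------------------------------

#' Negate a chunk by template
#'
#' Deterministic textual negation used to manufacture hard negatives for
#' triplet construction: the anchor is prefixed with a fixed negating clause.
#' Not idempotent — applying it twice prepends the clause twice.
#'
#' @param text Non-empty chunk text.
#' @return The negated text.
#' @export
#' @examples
#' negate_chunk("acute PE identified on CTPA")
negate_chunk <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("negate_chunk: empty text")
  paste0("No evidence of the following was found: ", text)
}

#' Build an (anchor, positive, negative) triplet dataset
#'
#' Triplets teach (or test) an embedding model to pull PE-affirming chunks
#' together and push negated or unrelated text away. Anchors are keyword
#' chunks from gold-positive charts; the positive is a different keyword
#' chunk (same chart preferred, else any gold-positive chart); the negative
#' is either the template-negated anchor (with probability
#' `negated_fraction`) or a keyword-free chunk from a gold-negative,
#' keyword-free chart. Anchors for which no distinct positive exists are
#' skipped with a warning. All random choices flow from one seeded
#' generator, recorded in the result's `seed` attribute.
#'
#' @param corpus A gold-labelled [chart_corpus()].
#' @param spec A [keyword_spec()].
#' @param negated_fraction Probability that a negative is the negated anchor.
#' @param seed Integer seed.
#' @param strategy,max_words Chunking parameters.
#' @return Data frame with columns `anchor`, `positive`, `negative`,
#'   `negative_source` (`"non_pe_chart"` or `"negated_anchor"`).
#' @export
build_triplets <- function(corpus, spec = keyword_spec(),
                           negated_fraction = 0.5, seed = 1L,
                           strategy = "paragraph", max_words = 128L) {
  stopifnot(inherits(corpus, "chart_corpus"),
            negated_fraction >= 0, negated_fraction <= 1)
  labels <- corpus_gold_labels(corpus)
  pieces <- lapply(corpus$charts, function(ch) {
    ck <- lapply(ch$notes, chunk_note, strategy = strategy,
                 max_words = max_words, patient_id = ch$patient_id)
    if (length(ck)) do.call(rbind, ck) else empty_chunks()
  })
  chunks <- do.call(rbind, c(pieces, list(empty_chunks())))
  rownames(chunks) <- NULL
  if (!nrow(chunks)) return(empty_triplets(seed))
  chunks$has_kw <- has_keyword(chunks$text, spec)
  chunks$gold <- labels[chunks$patient_id]

  anchors <- chunks[chunks$has_kw & chunks$gold %in% 1L, , drop = FALSE]
  if (!nrow(anchors)) return(empty_triplets(seed))

  kw_by_chart <- split(chunks$text[chunks$has_kw & chunks$gold %in% 1L],
                       chunks$patient_id[chunks$has_kw & chunks$gold %in% 1L])
  # negatives must come from gold-negative charts that are keyword-free
  kw_charts <- unique(chunks$patient_id[chunks$has_kw])
  neg_pool <- chunks$text[chunks$gold %in% 0L &
                            !(chunks$patient_id %in% kw_charts)]
  if (negated_fraction < 1 && !length(neg_pool)) {
    stop("build_triplets: no eligible negatives ",
         "(need a gold-negative chart without PE keywords)")
  }

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(anchors)), function(i) {
      a <- anchors$text[i]
      same <- setdiff(kw_by_chart[[anchors$patient_id[i]]], a)
      pos_pool <- if (length(same)) same else setdiff(anchors$text, a)
      if (!length(pos_pool)) return(NULL)
      p <- if (length(pos_pool) == 1L) pos_pool else sample(pos_pool, 1L)
      if (stats::runif(1) < negated_fraction) {
        list(anchor = a, positive = p, negative = negate_chunk(a),
             negative_source = "negated_anchor")
      } else {
        pool <- setdiff(neg_pool, c(a, p))
        if (!length(pool)) return(NULL)
        n <- if (length(pool) == 1L) pool else sample(pool, 1L)
        list(anchor = a, positive = p, negative = n,
             negative_source = "non_pe_chart")
      }
    })
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped > 0L) {
      warning(dropped, " anchor(s) skipped: no distinct positive/negative available")
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- do.call(rbind, lapply(rows, as.data.frame,
                                 stringsAsFactors = FALSE))
    if (is.null(out)) out <- empty_triplets(seed)[, ]
    attr(out, "seed") <- seed
    out
  })
}

empty_triplets <- function(seed) {
  out <- data.frame(anchor = character(0), positive = character(0),
                    negative = character(0), negative_source = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Triplet accuracy of an embedding backend
#'
#' The fraction of triplets for which the anchor embeds strictly closer (by
#' cosine) to its positive than to its negative; ties count as failures.
#'
#' @param triplets Data frame from [build_triplets()].
#' @param backend An [embedding_backend()].
#' @return Proportion in `[0, 1]`.
#' @export
triplet_accuracy <- function(triplets, backend) {
  if (!nrow(triplets)) stop("triplet_accuracy: empty triplet set")
  texts <- unique(c(triplets$anchor, triplets$positive, triplets$negative))
  emb <- embed_texts(backend, texts)
  rownames(emb) <- texts
  ok <- vapply(seq_len(nrow(triplets)), function(i) {
    a <- emb[triplets$anchor[i], ]
    cosine_similarity(a, emb[triplets$positive[i], ]) >
      cosine_similarity(a, emb[triplets$negative[i], ])
  }, logical(1))
  mean(ok)
}

# ---- reduction summary -----------------------------------------------------

#' Per-patient chunk statistics for one filtering stage
#'
#' @param chunks Chunk data frame.
#' @param patient_ids All patient ids of the corpus (patients with zero
#'   retained chunks must still appear).
#' @return Data frame with columns `patient_id`, `n_chunks`, `n_words`.
#' @export
chunk_stats <- function(chunks, patient_ids) {
  n_chunks <- stats::setNames(integer(length(patient_ids)), patient_ids)
  n_words <- n_chunks
  if (nrow(chunks)) {
    tc <- tapply(chunks$word_count, chunks$patient_id, length)
    tw <- tapply(chunks$word_count, chunks$patient_id, sum)
    n_chunks[names(tc)] <- as.integer(tc)
    n_words[names(tw)] <- as.integer(tw)
  }
  data.frame(patient_id = patient_ids, n_chunks = unname(n_chunks),
             n_words = unname(n_words), stringsAsFactors = FALSE)
}

#' Summarize text reduction across filtering stages
#'
#' For each stage (e.g. raw chunking, keyword filtering, semantic filtering)
#' reports the total chunk count plus the median and interquartile range of
#' per-patient chunk and word counts. Quartiles use linear interpolation
#' between closest ranks ([stats::quantile()] type 7); IQR conventions
#' differ between software, so this is stated explicitly.
#'
#' @param stage_stats Named list of per-stage data frames from
#'   [chunk_stats()]; all stages must cover the identical patient set.
#' @return Data frame, one row per stage, columns `stage`, `total_chunks`,
#'   `chunks_median`, `chunks_q1`, `chunks_q3`, `words_median`, `words_q1`,
#'   `words_q3`.
#' @export
summarize_reduction <- function(stage_stats) {
  stopifnot(is.list(stage_stats), length(stage_stats) >= 1L,
            !is.null(names(stage_stats)))
  ids <- lapply(stage_stats, function(s) sort(s$patient_id))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("summarize_reduction: stages cover different patient sets")
  }
  rows <- lapply(names(stage_stats), function(nm) {
    s <- stage_stats[[nm]]
    qc <- stats::quantile(s$n_chunks, c(.25, .5, .75), type = 7, names = FALSE)
    qw <- stats::quantile(s$n_words, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(stage = nm, total_chunks = sum(s$n_chunks),
               chunks_median = qc[2], chunks_q1 = qc[1], chunks_q3 = qc[3],
               words_median = qw[2], words_q1 = qw[1], words_q3 = qw[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
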