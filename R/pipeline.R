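# Pipeline orchestration: one resolved configuration drives
# generate/extract/detect/evaluate, every artifact is stamped with the
# configuration hash and seed, and per-stage counts are logged in the shape
# of a chunk-reduction table.

#' Resolved run configuration
#'
#' A flat, YAML-serialisable record of every knob of a pipeline run. The
#' two design axes of the screening study — keyword vs semantic retrieval,
#' and inclusion of discharge information — are ordinary fields here.
#'
#' @param corpus_path Path to a JSON-lines corpus (optional when a corpus
#'   object is passed to [run_pipeline()] directly).
#' @param method `"keyword"` or `"semantic"` retrieval.
#' @param include_discharge Feed recovered discharge sections to detection.
#' @param dialect Prompt dialect name.
#' @param backend Generation backend name; `"mock"` selects the rule-based
#'   mock.
#' @param strategy,max_words,overlap Chunking parameters.
#' @param top_percent,aggregation Semantic filter parameters.
#' @param embedding_dim Dimension of the hashing embedder.
#' @param max_chars Evidence character budget (`NULL` = unlimited).
#' @param n_boot,ci_level Bootstrap parameters.
#' @param granularity Surveillance granularity (`"year"`, `"year_quarter"`,
#'   `"year_month"`).
#' @param seed Integer seed stamped on artifacts and used for resampling.
#' @param out_dir Optional artifact directory.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(corpus_path = NULL,
                       method = c("keyword", "semantic"),
                       include_discharge = TRUE, dialect = "plain",
                       backend = "mock", strategy = "paragraph",
                       max_words = 128L, overlap = 0L, top_percent = 5,
                       aggregation = "max", embedding_dim = 256L,
                       max_chars = NULL, n_boot = 10000L, ci_level = 0.95,
                       granularity = "year", seed = 1L, out_dir = NULL) {
  structure(list(corpus_path = corpus_path, method = match.arg(method),
                 include_discharge = isTRUE(include_discharge),
                 dialect = dialect, backend = backend, strategy = strategy,
                 max_words = as.integer(max_words),
                 overlap = as.integer(overlap),
                 top_percent = as.numeric(top_percent),
                 aggregation = aggregation,
                 embedding_dim = as.integer(embedding_dim),
                 max_chars = max_chars, n_boot = as.integer(n_boot),
                 ci_level = ci_level, granularity = granularity,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The file form round-trips losslessly through [run_config()].
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()]; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

as_detection_config <- function(config) {
  detection_config(
    method = config$method, include_discharge = config$include_discharge,
    dialect = config$dialect, strategy = config$strategy,
    max_words = config$max_words, overlap = config$overlap,
    emb_backend = hash_embedding_backend(config$embedding_dim),
    sem_config = semantic_filter_config(config$top_percent,
                                        config$aggregation),
    max_chars = config$max_chars %||% Inf)
}

resolve_backend <- function(config, backend = NULL) {
  if (!is.null(backend)) return(backend)
  if (identical(config$backend, "mock")) return(mock_generation_backend())
  stop("unknown generation backend '", config$backend,
       "'; pass a generation_backend object")
}

log_event <- function(events, stage, ...) {
  c(events, list(c(list(stage = stage), list(...))))
}

#' Run the full screening pipeline
#'
#' Reads (or receives) a corpus, extracts evidence per chart, optionally
#' extracts discharge information, obtains a detection answer from the
#' generation backend, classifies it, and — when gold labels are present —
#' evaluates screening metrics with bootstrap CIs and the surveillance
#' trend at the configured granularity. Per-stage chunk counts are logged so
#' the reduction table can be reconstructed without re-running the filters.
#' When `config$out_dir` is set, predictions (TSV), metrics, surveillance
#' and reduction tables (JSON), the resolved configuration (YAML) and the
#' structured event log (JSON-lines) are written there, all stamped with the
#' configuration hash.
#'
#' @param config A [run_config()].
#' @param corpus Optional [chart_corpus()]; read from `config$corpus_path`
#'   otherwise.
#' @param backend Optional [generation_backend()] overriding
#'   `config$backend`.
#' @return An object of class `peae_run`: `predictions`, `metrics`,
#'   `surveillance`, `reduction`, `events`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), corpus = NULL,
                         backend = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(corpus)) {
    if (is.null(config$corpus_path)) {
      stop("run_pipeline: no corpus given and config$corpus_path is NULL")
    }
    if (!file.exists(config$corpus_path)) {
      stop("run_pipeline: corpus path does not exist: ", config$corpus_path)
    }
    corpus <- read_corpus(config$corpus_path)
  }
  backend <- resolve_backend(config, backend)
  dcfg <- as_detection_config(config)
  # the hash identifies the analysis configuration; artifact location is
  # deliberately excluded so re-running elsewhere yields the same tag
  cfg_hash <- fingerprint(unclass(config)[setdiff(names(config), "out_dir")])
  events <- list()
  events <- log_event(events, "load", n_charts = length(corpus$charts),
                      config_hash = cfg_hash)

  ids <- vapply(corpus$charts, `[[`, character(1), "patient_id")
  raw_stats <- data.frame(patient_id = ids, n_chunks = 0L, n_words = 0L,
                          stringsAsFactors = FALSE)
  kept_chunks <- vector("list", length(corpus$charts))
  rows <- vector("list", length(corpus$charts))
  for (k in seq_along(corpus$charts)) {
    ch <- corpus$charts[[k]]
    chunks <- extract_evidence(ch, method = dcfg$method, spec = dcfg$spec,
                               strategy = dcfg$strategy,
                               max_words = dcfg$max_words,
                               overlap = dcfg$overlap,
                               examples = dcfg$examples,
                               backend = dcfg$emb_backend,
                               config = dcfg$sem_config)
    raw_stats$n_chunks[k] <- attr(chunks, "n_raw_chunks")
    raw_stats$n_words[k] <- attr(chunks, "n_raw_words")
    kept_chunks[[k]] <- chunks[, c("patient_id", "note_id", "chunk_index",
                                   "start", "end", "text", "word_count",
                                   "timestamp"), drop = FALSE]
    r <- detect_peae(ch, dcfg, backend, chunks = chunks)
    rows[[k]] <- data.frame(patient_id = r$patient_id, label = r$label,
                            gold = ch$gold_label %||% NA_integer_,
                            prompt_hash = r$prompt_hash, flagged = r$flagged,
                            backend = backend$name, config_tag = cfg_hash,
                            stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, rows)
  rownames(predictions) <- NULL
  all_kept <- do.call(rbind, c(kept_chunks, list(empty_chunks())))
  filt_stats <- chunk_stats(all_kept, ids)
  stage_name <- if (config$method == "keyword") "keyword_filtered"
                else "semantic_filtered"
  reduction <- summarize_reduction(stats::setNames(
    list(raw_stats, filt_stats), c("raw", stage_name)))
  events <- log_event(events, "extract",
                      total_raw_chunks = sum(raw_stats$n_chunks),
                      total_kept_chunks = sum(filt_stats$n_chunks))
  events <- log_event(events, "detect",
                      n_positive = sum(predictions$label == 1L),
                      n_flagged = sum(predictions$flagged))

  metrics <- NULL
  surv <- NULL
  if (!anyNA(predictions$gold)) {
    preds <- stats::setNames(predictions$label, predictions$patient_id)
    golds <- stats::setNames(predictions$gold, predictions$patient_id)
    metrics <- bootstrap_metrics(preds, golds,
                                 eval_config(config$n_boot, config$ci_level,
                                             config$seed))
    surv <- surveillance(preds, golds, corpus, config$granularity)
    events <- log_event(events, "evaluate", n_boot = config$n_boot,
                        granularity = config$granularity)
  } else {
    events <- log_event(events, "evaluate", skipped = "missing gold labels")
  }

  run <- structure(list(predictions = predictions, metrics = metrics,
                        surveillance = surv, reduction = reduction,
                        events = events, config = config,
                        config_hash = cfg_hash),
                   class = "peae_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_predictions(run$predictions, file.path(out_dir, "predictions.tsv"))
  write_run_config(run$config, file.path(out_dir, "config.yaml"))
  if (!is.null(run$metrics)) {
    jsonlite::write_json(run$metrics, file.path(out_dir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$surveillance)) {
    s <- run$surveillance
    jsonlite::write_json(list(granularity = s$granularity, mse = s$mse,
                              pearson_r = s$pearson_r,
                              r_squared = s$r_squared, flags = s$flags,
                              series = s$series),
                         file.path(out_dir, "surveillance.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$reduction, file.path(out_dir, "reduction.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_lines <- vapply(run$events, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(file.path(out_dir, "events.jsonl"), open = "wb")
  on.exit(close(con))
  writeLines(log_lines, con, useBytes = TRUE)
  invisible(out_dir)
}

#' @export
print.peae_run <- function(x, ...) {
  cat(sprintf("<peae_run> %s/%s, %d charts, %d screened positive [%s]\n",
              x$config$method,
              if (x$config$include_discharge) "with-discharge"
              else "no-discharge",
              nrow(x$predictions), sum(x$predictions$label == 1L),
              x$config_hash))
  invisible(x)
}

#' Compare the four retrieval x discharge conditions
#'
#' Runs the pipeline over the 2x2 grid of retrieval method (keyword vs
#' semantic) and discharge-information inclusion, and tabulates the five
#' screening metrics with their bootstrap CIs, one row per condition in the
#' conventional column order. With `lenient = TRUE` a failing condition
#' contributes a failure record instead of aborting the grid.
#'
#' @param base_config A [run_config()] providing all other knobs.
#' @param corpus Optional [chart_corpus()] (else read from the config path).
#' @param backend Optional [generation_backend()].
#' @param lenient Keep going when a condition fails.
#' @return List with `table` (data frame: `retrieval`, `discharge`, then
#'   `<metric>` and `<metric>_ci` columns) and `failures` (named character
#'   vector of error messages, empty when all conditions ran).
#' @export
compare_conditions <- function(base_config = run_config(), corpus = NULL,
                               backend = NULL, lenient = FALSE) {
  grid <- expand.grid(method = c("keyword", "semantic"),
                      include_discharge = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rows <- list(); failures <- character(0)
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$method <- grid$method[g]
    cfg$include_discharge <- grid$include_discharge[g]
    cfg$out_dir <- NULL
    run <- tryCatch(run_pipeline(cfg, corpus = corpus, backend = backend),
                    error = function(e) e)
    cond <- sprintf("%s/%s", grid$method[g],
                    if (grid$include_discharge[g]) "discharge"
                    else "no-discharge")
    if (inherits(run, "error")) {
      if (!lenient) stop("compare_conditions: condition ", cond,
                         " failed: ", conditionMessage(run))
      failures[cond] <- conditionMessage(run)
      next
    }
    m <- run$metrics
    if (is.null(m)) {
      if (!lenient) stop("compare_conditions: no gold labels to score")
      failures[cond] <- "missing gold labels"
      next
    }
    row <- data.frame(retrieval = ifelse(grid$method[g] == "keyword",
                                         "KW", "SS"),
                      discharge = ifelse(grid$include_discharge[g], "Yes",
                                         "No"),
                      stringsAsFactors = FALSE)
    for (metric in c("ppv", "sensitivity", "specificity", "npv", "f1")) {
      mr <- m[m$metric == metric, ]
      row[[metric]] <- mr$boot_mean
      row[[paste0(metric, "_ci")]] <- sprintf("(%.2f-%.2f)", mr$ci_low,
                                              mr$ci_high)
    }
    rows[[cond]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  list(table = out, failures = failures)
}
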