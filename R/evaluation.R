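# Evaluation layer: screening metrics with bootstrap confidence intervals,
# population-level surveillance trend scoring, the ICD-code rule baseline,
# and cohort summarization.

align_preds_golds <- function(preds, golds) {
  if (!is.null(names(preds)) && !is.null(names(golds))) {
    unknown <- setdiff(names(preds), names(golds))
    if (length(unknown)) {
      stop("predictions for unknown patient id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    golds <- golds[names(preds)]
  } else if (length(preds) != length(golds)) {
    stop("preds and golds differ in length (", length(preds), " vs ",
         length(golds), ")")
  }
  if (!length(preds)) stop("empty prediction set")
  if (anyNA(preds) || anyNA(golds)) stop("NA in preds or golds")
  list(preds = as.integer(preds), golds = as.integer(golds))
}

#' Confusion counts from aligned binary vectors
#'
#' @param preds,golds Binary vectors of equal length (aligned by position,
#'   or by patient id when both are named).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(preds, golds) {
  a <- align_preds_golds(preds, golds)
  structure(list(tp = sum(a$preds == 1L & a$golds == 1L),
                 fp = sum(a$preds == 1L & a$golds == 0L),
                 tn = sum(a$preds == 0L & a$golds == 0L),
                 fn = sum(a$preds == 0L & a$golds == 1L)),
            class = "confusion_counts")
}

metric_from_counts <- function(num, den) {
  if (den == 0) c(value = 0, degenerate = 1) else c(value = 100 * num / den,
                                                    degenerate = 0)
}

#' The five screening metrics from confusion counts
#'
#' PPV, sensitivity, specificity, NPV and F1, reported as percentages. A
#' metric whose denominator is zero is reported as 0 with a `degenerate`
#' flag (the convention also used to skip degenerate bootstrap resamples).
#'
#' @param counts A [confusion()] result.
#' @return Data frame with columns `metric`, `value` (percent),
#'   `degenerate`.
#' @export
screen_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ppv <- metric_from_counts(counts$tp, counts$tp + counts$fp)
  sens <- metric_from_counts(counts$tp, counts$tp + counts$fn)
  spec <- metric_from_counts(counts$tn, counts$tn + counts$fp)
  npv <- metric_from_counts(counts$tn, counts$tn + counts$fn)
  f1 <- if (ppv[["value"]] + sens[["value"]] == 0) {
    c(value = 0, degenerate = 1)
  } else {
    c(value = 2 * ppv[["value"]] * sens[["value"]] /
        (ppv[["value"]] + sens[["value"]]),
      degenerate = max(ppv[["degenerate"]], sens[["degenerate"]]))
  }
  m <- rbind(ppv = ppv, sensitivity = sens, specificity = spec, npv = npv,
             f1 = f1)
  data.frame(metric = rownames(m), value = unname(m[, "value"]),
             degenerate = unname(m[, "degenerate"]) == 1,
             stringsAsFactors = FALSE)
}

#' F1 score from PPV and sensitivity percentages
#'
#' Harmonic mean `2ps/(p+s)`, rounded to two decimals as conventionally
#' reported.
#'
#' @param ppv,sensitivity Percentages in `[0, 100]`, not both zero.
#' @return F1 as a percentage, rounded to 2 decimals.
#' @export
#' @examples
#' f1_score(14.04, 100.0)  # 24.62
f1_score <- function(ppv, sensitivity) {
  stopifnot(ppv >= 0, ppv <= 100, sensitivity >= 0, sensitivity <= 100)
  if (ppv + sensitivity == 0) stop("f1_score: PPV and sensitivity both zero")
  round(2 * ppv * sensitivity / (ppv + sensitivity), 2)
}

#' Evaluation configuration
#'
#' @param n_boot Bootstrap resample count (default 10 000).
#' @param ci_level Confidence level of the percentile interval.
#' @param seed Integer seed for resampling.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_boot = 10000L, ci_level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 1L, ci_level > 0, ci_level < 1)
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# per-resample metric values from pair codes (1 tp, 2 fp, 3 fn, 4 tn),
# sampled in blocks to bound memory; returns n_boot x 5 matrix with NA for
# degenerate resamples
boot_metric_matrix <- function(codes, n_boot, block = 500L) {
  n <- length(codes)
  out <- matrix(NA_real_, n_boot, 5,
                dimnames = list(NULL, c("ppv", "sensitivity", "specificity",
                                        "npv", "f1")))
  done <- 0L
  while (done < n_boot) {
    b <- min(block, n_boot - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), n, b)
    cm <- matrix(codes[idx], n, b)
    tp <- colSums(cm == 1L); fp <- colSums(cm == 2L)
    fn <- colSums(cm == 3L); tn <- colSums(cm == 4L)
    rows <- done + seq_len(b)
    out[rows, "ppv"] <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA)
    out[rows, "sensitivity"] <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA)
    out[rows, "specificity"] <- ifelse(tn + fp > 0, 100 * tn / (tn + fp), NA)
    out[rows, "npv"] <- ifelse(tn + fn > 0, 100 * tn / (tn + fn), NA)
    p <- out[rows, "ppv"]; s <- out[rows, "sensitivity"]
    out[rows, "f1"] <- ifelse(!is.na(p) & !is.na(s) & p + s > 0,
                              2 * p * s / (p + s),
                              ifelse(!is.na(p) & !is.na(s), 0, NA))
    done <- done + b
  }
  out
}

#' Bootstrap point estimates and confidence intervals for screening metrics
#'
#' Resamples patients with replacement (`n` draws per resample, the analysis
#' unit being the patient), recomputes the five metrics per resample, and
#' summarizes each metric's distribution by its mean and the percentile
#' interval at `ci_level`. Resamples in which a metric's denominator is zero
#' are skipped for that metric and counted in `n_degenerate`. Fully
#' reproducible under `config$seed`.
#'
#' @param preds,golds Binary vectors (see [confusion()]).
#' @param config An [eval_config()].
#' @return Data frame with columns `metric`, `point`, `boot_mean`, `ci_low`,
#'   `ci_high`, `n_degenerate` (all percentages except the count). A metric
#'   degenerate in every resample has `NA` summaries.
#' @export
bootstrap_metrics <- function(preds, golds, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  a <- align_preds_golds(preds, golds)
  point <- screen_metrics(confusion(a$preds, a$golds))
  codes <- ifelse(a$preds == 1L, ifelse(a$golds == 1L, 1L, 2L),
                  ifelse(a$golds == 1L, 3L, 4L))
  bm <- with_seed(config$seed,
                  boot_metric_matrix(codes, config$n_boot))
  alpha <- (1 - config$ci_level) / 2
  rows <- lapply(colnames(bm), function(m) {
    v <- bm[, m]
    nd <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(metric = m, point = point$value[point$metric == m],
                        boot_mean = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_degenerate = nd,
                        stringsAsFactors = FALSE))
    }
    ci <- stats::quantile(v, c(alpha, 1 - alpha), type = 7, names = FALSE)
    data.frame(metric = m, point = point$value[point$metric == m],
               boot_mean = mean(v), ci_low = ci[1], ci_high = ci[2],
               n_degenerate = nd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_boot") <- config$n_boot
  attr(out, "ci_level") <- config$ci_level
  attr(out, "seed") <- config$seed
  out
}

#' Render a metric report as a display table
#'
#' One row per metric in the conventional column order (PPV, Sensitivity,
#' Specificity, NPV, F1), values formatted as `point (lo-hi)`.
#'
#' @param report A [bootstrap_metrics()] result.
#' @param digits Decimals (default 2).
#' @return Data frame with columns `metric`, `display`.
#' @export
render_metric_table <- function(report, digits = 2) {
  ord <- c("ppv", "sensitivity", "specificity", "npv", "f1")
  report <- report[match(ord, report$metric), ]
  disp <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                  report$boot_mean, report$ci_low, report$ci_high)
  data.frame(metric = c("PPV", "Sensitivity", "Specificity", "NPV",
                        "F1 score"),
             display = disp, stringsAsFactors = FALSE)
}

# ---- surveillance ------------------------------------------------------------

period_key <- function(dates, granularity = c("year", "year_quarter",
                                              "year_month")) {
  granularity <- match.arg(granularity)
  switch(granularity,
         year = format(dates, "%Y"),
         year_quarter = paste0(format(dates, "%Y"), "-Q",
                               (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L),
         year_month = format(dates, "%Y-%m"))
}

#' Surveillance trend scoring at a time granularity
#'
#' Bins patients into periods by admission date (or discharge date via
#' `assign_by`), computes the actual and predicted incidence proportion per
#' period (positives / patients admitted that period), and scores the
#' agreement of the two aligned series by mean squared error, Pearson
#' correlation, and R-squared (the squared Pearson correlation). With fewer
#' than two periods the trend metrics are undefined; with a zero-variance
#' actual series the correlation is undefined; both cases are flagged rather
#' than raised.
#'
#' @param preds,golds Binary vectors named by patient id, or aligned with
#'   `corpus$charts`.
#' @param corpus The [chart_corpus()] providing admission dates.
#' @param granularity `"year"`, `"year_quarter"`, or `"year_month"`.
#' @param assign_by Date used for period assignment.
#' @return An object of class `surveillance_report`: `granularity`, `series`
#'   (data frame `period`, `n`, `actual`, `predicted`), `mse`, `pearson_r`,
#'   `r_squared`, `flags`.
#' @export
surveillance <- function(preds, golds, corpus,
                         granularity = c("year", "year_quarter",
                                         "year_month"),
                         assign_by = c("admission", "discharge")) {
  granularity <- match.arg(granularity)
  assign_by <- match.arg(assign_by)
  stopifnot(inherits(corpus, "chart_corpus"))
  ids <- vapply(corpus$charts, `[[`, character(1), "patient_id")
  dates <- as.Date(vapply(corpus$charts, function(ch) {
    iso_date(if (assign_by == "admission") ch$admission_date
             else ch$discharge_date)
  }, character(1)))
  if (!is.null(names(preds))) {
    missing_ids <- setdiff(ids, names(preds))
    if (length(missing_ids)) {
      stop("no prediction for patient id(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    preds <- preds[ids]
    golds <- golds[ids]
  } else {
    stopifnot(length(preds) == length(ids), length(golds) == length(ids))
  }
  key <- period_key(dates, granularity)
  agg <- function(x) tapply(as.integer(x), key, mean)
  nper <- tapply(key, key, length)
  actual <- agg(golds)
  predicted <- agg(preds)
  stopifnot(identical(names(actual), names(predicted)))
  series <- data.frame(period = names(actual), n = as.integer(nper),
                       actual = as.numeric(actual),
                       predicted = as.numeric(predicted),
                       stringsAsFactors = FALSE)
  series <- series[order(series$period), ]
  rownames(series) <- NULL
  flags <- character(0)
  mse <- pearson <- r2 <- NA_real_
  if (nrow(series) < 2L) {
    flags <- c(flags, "fewer_than_two_periods")
  } else {
    mse <- mean((series$actual - series$predicted)^2)
    if (stats::sd(series$actual) == 0) {
      flags <- c(flags, "zero_variance_actual")
    } else if (stats::sd(series$predicted) == 0) {
      flags <- c(flags, "zero_variance_predicted")
    } else {
      pearson <- stats::cor(series$actual, series$predicted)
      r2 <- pearson^2
    }
  }
  structure(list(granularity = granularity, series = series, mse = mse,
                 pearson_r = pearson, r_squared = r2, flags = flags),
            class = "surveillance_report")
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat(sprintf("<surveillance_report> %s: %d periods, MSE %.4g, r %.3f, R2 %.3f\n",
              x$granularity, nrow(x$series), x$mse, x$pearson_r,
              x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# ---- ICD baseline ------------------------------------------------------------

#' ICD-code rule baseline for one chart
#'
#' Flags a chart positive when any coded diagnosis matches one of the
#' configured ICD-10 prefixes (default `"I26"`, pulmonary embolism) and,
#' when `require_not_poa`, was not marked present on admission. The exact
#' code list used by any given discharge-abstract rule is jurisdictional;
#' the prefix set is configuration.
#'
#' @param chart A [patient_chart()].
#' @param code_prefixes Character vector of ICD-10 code prefixes.
#' @param require_not_poa Require the diagnosis-type indicator to say the
#'   condition was not present on admission.
#' @return 0 or 1.
#' @export
icd_baseline <- function(chart, code_prefixes = "I26",
                         require_not_poa = TRUE) {
  dx <- chart$diagnosis_codes
  if (is.null(dx) || !nrow(dx)) return(0L)
  hit <- Reduce(`|`, lapply(code_prefixes, function(p) startsWith(dx$code, p)))
  if (require_not_poa) hit <- hit & !dx$present_on_admission
  as.integer(any(hit))
}

#' ICD baseline over a corpus
#'
#' @param corpus A [chart_corpus()].
#' @inheritParams icd_baseline
#' @return Named integer vector of baseline labels keyed by patient id.
#' @export
icd_baseline_corpus <- function(corpus, code_prefixes = "I26",
                                require_not_poa = TRUE) {
  stats::setNames(
    vapply(corpus$charts, icd_baseline, integer(1),
           code_prefixes = code_prefixes, require_not_poa = require_not_poa),
    vapply(corpus$charts, `[[`, character(1), "patient_id"))
}

# ---- cohort summarization ----------------------------------------------------

#' Test a contingency table for independence
#'
#' Chi-square test without continuity correction by default (Fisher's exact
#' available), with the reporting convention that p-values below 0.001 are
#' displayed as `"<.001"`.
#'
#' @param counts Integer matrix (levels x groups).
#' @param method `"chisq"` or `"fisher"`.
#' @return List with `statistic`, `p_value`, `p_display`, `method`.
#' @export
#' @examples
#' independence_test(matrix(c(4, 36, 4877, 5149), nrow = 2))
independence_test <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (method == "chisq") {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(counts)
    stat <- NA_real_
  }
  p <- unname(ht$p.value)
  list(statistic = stat, p_value = p,
       p_display = if (p < 0.001) "<.001" else sub("^0\\.", ".",
                                                   sprintf("%.3f", p)),
       method = method)
}

band_age <- function(age) {
  cut(age, c(-Inf, 49, 64, 74, Inf),
      labels = c("<50", "50-64", "65-74", ">=75"))
}

band_comorbidity <- function(k) {
  cut(k, c(-Inf, 0, 1, Inf), labels = c("0", "1", ">=2"))
}

band_los <- function(days) {
  cut(days, c(-Inf, 4, Inf), labels = c("1-4 days", ">=5 days"))
}

#' Cohort characteristics by PEAE status
#'
#' Counts and column percentages of age bands, sex, in-hospital death,
#' comorbidity bands and length-of-stay bands, split by gold PEAE status,
#' with a per-variable test of independence (chi-square without continuity
#' correction by default). Variables entirely missing from the corpus are
#' omitted.
#'
#' @param corpus A gold-labelled [chart_corpus()].
#' @param method Test passed to [independence_test()].
#' @return List with `table` (data frame: `variable`, `level`, `n_all`,
#'   `pct_all`, `n_peae`, `pct_peae`, `n_non_peae`, `pct_non_peae`) and
#'   `tests` (data frame: `variable`, `statistic`, `p_value`, `p_display`).
#' @export
summarize_cohort <- function(corpus, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(corpus, "chart_corpus"))
  gold <- corpus_gold_labels(corpus)
  if (anyNA(gold)) stop("summarize_cohort: gold labels missing")
  chs <- corpus$charts
  los <- vapply(chs, function(ch) {
    as.integer(ch$discharge_date - ch$admission_date) + 1L   # inclusive days
  }, integer(1))
  vars <- list(
    age = band_age(vapply(chs, `[[`, integer(1), "age")),
    sex = factor(vapply(chs, `[[`, character(1), "sex"),
                 levels = c("F", "M"), labels = c("Female", "Male")),
    death_in_hospital = factor(
      ifelse(vapply(chs, function(ch) isTRUE(ch$died_in_hospital),
                    logical(1)), "Died", "Survived"),
      levels = c("Died", "Survived")),
    n_comorbidities = band_comorbidity(
      vapply(chs, `[[`, integer(1), "n_comorbidities")),
    length_of_stay = band_los(los))
  status <- factor(ifelse(gold == 1L, "PEAE", "non-PEAE"),
                   levels = c("PEAE", "non-PEAE"))
  tab_rows <- list(); test_rows <- list()
  for (v in names(vars)) {
    x <- vars[[v]]
    if (all(is.na(x))) next
    ct <- table(x, status)
    if (nrow(ct) < 2L) next
    tt <- independence_test(as.matrix(ct), method)
    test_rows[[v]] <- data.frame(variable = v, statistic = tt$statistic,
                                 p_value = tt$p_value,
                                 p_display = tt$p_display,
                                 stringsAsFactors = FALSE)
    n_all <- rowSums(ct)
    tab_rows[[v]] <- data.frame(
      variable = v, level = rownames(ct),
      n_all = as.integer(n_all),
      pct_all = round(100 * n_all / sum(n_all), 1),
      n_peae = as.integer(ct[, "PEAE"]),
      pct_peae = round(100 * ct[, "PEAE"] / max(1, sum(ct[, "PEAE"])), 1),
      n_non_peae = as.integer(ct[, "non-PEAE"]),
      pct_non_peae = round(100 * ct[, "non-PEAE"] /
                             max(1, sum(ct[, "non-PEAE"])), 1),
      stringsAsFactors = FALSE)
  }
  out_tab <- do.call(rbind, tab_rows)
  rownames(out_tab) <- NULL
  list(table = out_tab,
       tests = do.call(rbind, test_rows),
       n = length(chs), n_peae = sum(gold == 1L),
       prevalence_pct = round(100 * mean(gold == 1L), 1))
}
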