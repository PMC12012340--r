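test_that("confusion tallies the 2x2 and validates alignment", {
  c1 <- confusion(c(1L, 1L), c(1L, 1L))
  expect_identical(unlist(c1[c("tp", "fp", "tn", "fn")]),
                   c(tp = 2L, fp = 0L, tn = 0L, fn = 0L))
  c2 <- confusion(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  expect_identical(unlist(c2[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1L, 0L), c(1L)), "length")
  expect_error(confusion(c(P9 = 1L), c(P1 = 1L)), "unknown")
  # named alignment reorders
  c3 <- confusion(c(a = 1L, b = 0L), c(b = 0L, a = 1L))
  expect_identical(c3$tp, 1L)
  expect_identical(c3$tn, 1L)
})

test_that("the five screening metrics match hand computation", {
  perfect <- screen_metrics(confusion(rep(c(1L, 0L), each = 10),
                                      rep(c(1L, 0L), each = 10)))
  expect_equal(perfect$value, rep(100, 5))

  m <- screen_metrics(structure(list(tp = 3L, fp = 1L, tn = 4L, fn = 2L),
                                class = "confusion_counts"))
  expect_equal(m$value[m$metric == "ppv"], 75)
  expect_equal(m$value[m$metric == "sensitivity"], 60)
  expect_equal(m$value[m$metric == "specificity"], 80)
  expect_equal(m$value[m$metric == "npv"], 400 / 6, tolerance = 1e-10)
  expect_equal(m$value[m$metric == "f1"], 200 * 0.75 * 0.6 / 1.35,
               tolerance = 1e-10)

  z <- screen_metrics(structure(list(tp = 0L, fp = 5L, tn = 0L, fn = 0L),
                                class = "confusion_counts"))
  expect_equal(z$value[z$metric == "ppv"], 0)
  expect_equal(z$value[z$metric == "f1"], 0)
  expect_true(z$degenerate[z$metric == "sensitivity"])
})

test_that("metrics equal a brute-force recount on random corpora", {
  set.seed(17)
  for (n in c(10, 500, 10000)) {
    gold <- rbinom(n, 1, 0.3)
    pred <- ifelse(runif(n) < 0.8, gold, 1L - gold)
    m <- screen_metrics(confusion(pred, gold))
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {          # deliberate element-wise recount
      if (pred[i] == 1 && gold[i] == 1) tp <- tp + 1
      if (pred[i] == 1 && gold[i] == 0) fp <- fp + 1
      if (pred[i] == 0 && gold[i] == 0) tn <- tn + 1
      if (pred[i] == 0 && gold[i] == 1) fn <- fn + 1
    }
    expect_equal(m$value[m$metric == "ppv"], 100 * tp / (tp + fp))
    expect_equal(m$value[m$metric == "sensitivity"], 100 * tp / (tp + fn))
    expect_equal(m$value[m$metric == "specificity"], 100 * tn / (tn + fp))
    expect_equal(m$value[m$metric == "npv"], 100 * tn / (tn + fn))
  }
})

test_that("f1 reproduces harmonic-mean identities and internal consistency", {
  expect_equal(f1_score(14.04, 100.0), 24.62)
  expect_equal(f1_score(37.5, 14.52), 20.93)
  expect_equal(f1_score(8.85, 100.0), 16.26)
  expect_equal(f1_score(44.4, 44.4), 44.4)
  expect_error(f1_score(0, 0), "both zero")

  m <- screen_metrics(structure(list(tp = 31L, fp = 13L, tn = 40L, fn = 7L),
                                class = "confusion_counts"))
  expect_equal(f1_score(m$value[m$metric == "ppv"],
                        m$value[m$metric == "sensitivity"]),
               round(m$value[m$metric == "f1"], 2))
})

test_that("bootstrap CIs are reproducible, contain the point, and collapse at zero variance", {
  gold <- rep(c(1L, 0L), c(8, 22))
  exact <- bootstrap_metrics(gold, gold, eval_config(n_boot = 400, seed = 2))
  expect_equal(exact$ci_low, rep(100, 5))
  expect_equal(exact$ci_high, rep(100, 5))
  expect_equal(exact$boot_mean, rep(100, 5))

  set.seed(3)
  pred <- ifelse(runif(30) < 0.8, gold, 1L - gold)
  a <- bootstrap_metrics(pred, gold, eval_config(n_boot = 1000, seed = 9))
  b <- bootstrap_metrics(pred, gold, eval_config(n_boot = 1000, seed = 9))
  expect_identical(a, b)
  expect_true(all(a$point >= a$ci_low - 1e-9 & a$point <= a$ci_high + 1e-9))
  expect_true(all(a$ci_low <= a$boot_mean & a$boot_mean <= a$ci_high))

  # boot mean approaches the point estimate as resamples grow
  errs <- vapply(c(100L, 1000L, 10000L), function(nb) {
    bm <- bootstrap_metrics(pred, gold, eval_config(n_boot = nb, seed = 5))
    max(abs(bm$boot_mean - bm$point))
  }, numeric(1))
  expect_lt(errs[3], 1.5)
})

test_that("degenerate resamples are skipped and counted per metric", {
  # one positive in 12: many resamples lack positives entirely
  gold <- c(1L, rep(0L, 11))
  bm <- bootstrap_metrics(gold, gold, eval_config(n_boot = 500, seed = 4))
  expect_gt(bm$n_degenerate[bm$metric == "sensitivity"], 0)
  expect_true(all(is.finite(bm$boot_mean)))
})

test_that("surveillance scores aligned incidence series per period", {
  # 3 years x 100 patients; actual (.02,.04,.06) vs predicted (.03,.03,.06)
  charts <- list(); gold <- integer(0); pred <- integer(0); k <- 0
  plan <- list(c(2018, 2, 3), c(2019, 4, 3), c(2020, 6, 6))
  for (p in plan) {
    for (i in 1:100) {
      k <- k + 1
      charts[[k]] <- fix_chart(sprintf("P%03d", k), notes = list(),
                               admission = sprintf("%d-06-01", p[1]),
                               discharge = sprintf("%d-06-05", p[1]),
                               gold = as.integer(i <= p[2]))
      gold <- c(gold, as.integer(i <= p[2]))
      pred <- c(pred, as.integer(i <= p[3]))
    }
  }
  corp <- chart_corpus(charts)
  names(gold) <- names(pred) <- sprintf("P%03d", 1:300)
  s <- surveillance(pred, gold, corp, "year")
  expect_equal(s$series$actual, c(0.02, 0.04, 0.06))
  expect_equal(s$series$predicted, c(0.03, 0.03, 0.06))
  expect_equal(s$mse, (1e-4 + 1e-4 + 0) / 3)
  expect_equal(s$pearson_r, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(s$r_squared, 0.75, tolerance = 1e-12)

  ident <- surveillance(gold, gold, corp, "year")
  expect_equal(ident$mse, 0)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$r_squared, 1)

  single <- chart_corpus(charts[1:100])
  s1 <- surveillance(pred[1:100], gold[1:100], single, "year")
  expect_true("fewer_than_two_periods" %in% s1$flags)
  expect_true(is.na(s1$pearson_r))

  flat_gold <- stats::setNames(rep(0L, 300), names(gold))
  s0 <- surveillance(pred, flat_gold, corp, "year")
  expect_true("zero_variance_actual" %in% s0$flags)
  expect_true(is.na(s0$pearson_r))
})

test_that("aggregation reduces per-period incidence error variance", {
  # errors come from independent per-patient false positives, so coarser
  # bins must shrink the error variance roughly linearly
  wins <- 0L
  for (s in 1:12) {
    g <- generate_corpus(generator_config(n_patients = 600,
                                          prevalence = 0.05,
                                          seed = 500 + s))
    pr <- detect_corpus(g$corpus, detection_config(include_discharge = FALSE),
                        mock_generation_backend())
    preds <- stats::setNames(pr$label, pr$patient_id)
    golds <- stats::setNames(pr$gold, pr$patient_id)
    yr <- surveillance(preds, golds, g$corpus, "year")
    mo <- surveillance(preds, golds, g$corpus, "year_month")
    v_yr <- stats::var(yr$series$actual - yr$series$predicted)
    v_mo <- stats::var(mo$series$actual - mo$series$predicted)
    if (v_yr < v_mo) wins <- wins + 1L
  }
  expect_gte(wins, 10L)
})

test_that("the ICD rule baseline honors prefixes and the POA flag", {
  ch <- fix_chart(dx = diagnosis_codes("I26.9", FALSE))
  expect_identical(icd_baseline(ch), 1L)
  expect_identical(icd_baseline(fix_chart(dx = diagnosis_codes())), 0L)
  poa <- fix_chart(dx = diagnosis_codes("I26.0", TRUE))
  expect_identical(icd_baseline(poa), 0L)
  expect_identical(icd_baseline(poa, require_not_poa = FALSE), 1L)
  other <- fix_chart(dx = diagnosis_codes(c("J18.9", "I10"), c(FALSE, FALSE)))
  expect_identical(icd_baseline(other), 0L)
  expect_identical(icd_baseline(other, code_prefixes = c("I10", "I26")), 1L)
  expect_error(diagnosis_codes("notacode"), "invalid")
})

test_that("cohort summaries report bands, percentages and independence tests", {
  even <- independence_test(matrix(c(10, 20, 30, 60), nrow = 2))
  expect_equal(unname(even$statistic), 0)
  expect_equal(even$p_value, 1)

  los <- independence_test(matrix(c(4, 36, 4877, 5149), nrow = 2))
  expect_lt(los$p_value, 0.001)
  expect_identical(los$p_display, "<.001")
  expect_false(is.na(independence_test(matrix(c(4, 36, 4877, 5149), 2),
                                       "fisher")$p_value))

  g <- generate_corpus(generator_config(n_patients = 400, prevalence = 0.08,
                                        seed = 12))
  s <- summarize_cohort(g$corpus)
  expect_identical(s$n, 400L)
  expect_equal(s$prevalence_pct,
               round(100 * mean(corpus_gold_labels(g$corpus) == 1L), 1))
  expect_true(all(c("age", "sex", "length_of_stay") %in% s$table$variable))
  los_rows <- s$table[s$table$variable == "length_of_stay", ]
  expect_equal(sum(los_rows$n_all), 400L)
  expect_true(all(s$tests$p_value >= 0 & s$tests$p_value <= 1))

  unlabelled <- chart_corpus(list(fix_chart("P1")))
  expect_error(summarize_cohort(unlabelled), "gold")
})
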