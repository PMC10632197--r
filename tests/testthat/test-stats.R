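test_that("exact binomial interval matches closed forms and the stats oracle", {
  # x = n: lower bound has the closed form (alpha/2)^(1/n)
  ci <- clopper_pearson_ci(8, 8)
  expect_equal(ci[["lower"]], 0.025^(1 / 8), tolerance = 1e-12)
  expect_equal(ci[["upper"]], 1)
  expect_equal(clopper_pearson_ci(0, 5)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(0, 5)[["upper"]], 1 - 0.025^(1 / 5),
               tolerance = 1e-12)
  # independent oracle: binom.test inverts the binomial test directly
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:400, 1); x <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson_ci(x, n)),
                 as.numeric(stats::binom.test(x, n)$conf.int),
                 tolerance = 1e-9, info = sprintf("x=%d n=%d", x, n))
  }
  expect_error(clopper_pearson_ci(9, 8), "x must be")
  expect_error(clopper_pearson_ci(1, 0), "n must be")
})

test_that("Wilson interval matches the score-test oracle and is symmetric at half", {
  # prop.test without continuity correction inverts the score test (Wilson)
  set.seed(6)
  for (i in 1:25) {
    n <- sample(1:400, 1); x <- sample(0:n, 1)
    expect_equal(unname(wilson_ci(x, n)),
                 as.numeric(stats::prop.test(x, n, correct = FALSE)$conf.int),
                 tolerance = 1e-9, info = sprintf("x=%d n=%d", x, n))
  }
  ci <- wilson_ci(25, 50)
  z <- qnorm(0.975)
  centre <- (0.5 + z^2 / 100) / (1 + z^2 / 50)
  expect_equal(unname(ci[["upper"]] - centre), unname(centre - ci[["lower"]]),
               tolerance = 1e-12)
  # closed form at x = n: the lower bound reduces to n / (n + z^2)
  z <- qnorm(0.975)
  expect_equal(wilson_ci(8, 8)[["lower"]], 8 / (8 + z^2), tolerance = 1e-12)
  expect_equal(wilson_ci(8, 8)[["lower"]], 0.6756, tolerance = 1e-3)
  expect_equal(wilson_ci(8, 8)[["upper"]], 1)
})

test_that("both interval methods contain the point and tighten with n", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:200, 1); x <- sample(0:n, 1)
    for (f in list(clopper_pearson_ci, wilson_ci)) {
      ci <- f(x, n)
      expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
      expect_true(ci[["lower"]] <= x / n && x / n <= ci[["upper"]])
      wider <- f(x, n); narrower <- f(4 * x, 4 * n)
      expect_lt(narrower[["upper"]] - narrower[["lower"]],
                wider[["upper"]] - wider[["lower"]] + 1e-12)
    }
  }
})

test_that("predictive-value logit interval: point by Bayes, bounds on the logit scale", {
  est <- predictive_value_ci_logit("PPV", se = 1, sp = 360 / 406, n1 = 8, n0 = 406,
                                   prevalence = 8 / 414)
  expect_equal(est$point, 8 / 54, tolerance = 1e-12)
  expect_equal(round_half_up(100 * est$lower, 1), 11.7)
  expect_equal(round_half_up(100 * est$upper, 1), 18.6)
  expect_identical(est$method, "mercaldo_logit")

  # perfect sensitivity leaves the NPV variance undefined: point, no bounds
  npv <- predictive_value_ci_logit("NPV", se = 1, sp = 360 / 406, n1 = 8, n0 = 406,
                                   prevalence = 8 / 414)
  expect_equal(npv$point, 1)
  expect_identical(npv$method, "none")
  expect_true(is.na(npv$lower))

  # an uninformative test returns the prevalence
  expect_equal(predictive_value_ci_logit("PPV", 0.5, 0.5, 10, 10, 0.5)$point, 0.5)
  expect_error(predictive_value_ci_logit("PPV", 1, 0.9, 0, 10), "n1 and n0")
})

test_that("accuracy report reproduces ratios from per-patient labels (brute force)", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    truth <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.3, 0.7))
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    ids <- sprintf("p%03d", seq_len(n))
    m <- build_confusion_matrix(ids[pos],
                                data.frame(patient_id = ids, brain_death = truth),
                                ids)
    # brute-force recount straight from the labels
    expect_equal(m$tp, sum(pos & truth))
    expect_equal(m$fp, sum(pos & !truth))
    expect_equal(m$fn, sum(!pos & truth))
    expect_equal(m$tn, sum(!pos & !truth))
    rep <- diagnostic_metrics(m)
    if (any(truth)) expect_equal(rep$sensitivity$point, mean(pos[truth]))
    if (any(!truth)) expect_equal(rep$specificity$point, mean(!pos[!truth]))
    if (any(pos)) expect_equal(rep$ppv$point, mean(truth[pos]))
    if (any(!pos)) expect_equal(rep$npv$point, mean(!truth[!pos]))
    expect_equal(rep$accuracy$point, mean(pos == truth))
    # identity: accuracy * N = tp + tn
    expect_equal(rep$accuracy$point * n, m$tp + m$tn)
    # Bayes consistency at the cohort prevalence
    if (any(pos) && any(truth) && any(!truth)) {
      se <- m$tp / (m$tp + m$fn); sp <- m$tn / (m$tn + m$fp); p <- mean(truth)
      expect_equal(rep$ppv$point, se * p / (se * p + (1 - sp) * (1 - p)),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate denominators are reported as undefined, never 0 or 1", {
  rep0 <- diagnostic_metrics(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(rep0$sensitivity$point))
  expect_identical(rep0$sensitivity$method, "none")
  expect_equal(rep0$specificity$point, 1)
  expect_true(is.na(rep0$ppv$point))
  full <- diagnostic_metrics(confusion_matrix(5, 0, 0, 0))
  expect_equal(full$sensitivity$point, 1)
  expect_true(is.na(full$specificity$point))
})

test_that("confusion matrix construction validates membership", {
  expect_error(build_confusion_matrix("ghost",
                                      data.frame(patient_id = "a", brain_death = 0),
                                      "a"),
               "not in cohort")
  m <- build_confusion_matrix(character(),
                              data.frame(patient_id = letters[1:10],
                                         brain_death = rep(0, 10)))
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]), c(tp = 0, fp = 0, fn = 0, tn = 10))
  m2 <- build_confusion_matrix(letters[1:4],
                               data.frame(patient_id = letters[1:4],
                                          brain_death = rep(1, 4)))
  expect_equal(unlist(m2[c("tp", "fp", "fn", "tn")]), c(tp = 4, fp = 0, fn = 0, tn = 0))
})

test_that("subgroup semantics: repeat-only positivity vs cohort restriction", {
  # cohort shaped like the study: 414 patients, 8 brain death all detected,
  # 54 screen-positive of whom 34 repeat-detected (7 brain death among them)
  n <- 414
  ids <- sprintf("p%03d", 1:n)
  bd <- c(rep(TRUE, 8), rep(FALSE, n - 8))
  n_notif <- integer(n)
  n_notif[1:7] <- 5          # brain death, repeat-detected
  n_notif[8] <- 1            # brain death, detected once
  n_notif[9:35] <- 4         # 27 false positives repeat-detected
  n_notif[36:54] <- 1        # 19 false positives detected once
  tab <- data.frame(patient_id = ids, brain_death = bd,
                    n_notifications = n_notif,
                    screen_positive = n_notif >= 1,
                    repeat_detected = n_notif >= 2,
                    ventilated = c(rep(TRUE, 49), rep(FALSE, 5),
                                   rep(TRUE, 125), rep(FALSE, 235)))

  whole <- subgroup_metrics(tab)
  expect_equal(whole$specificity$point, 360 / 406)

  rep_only <- subgroup_metrics(tab, positive_filter = function(d) d$repeat_detected)
  expect_equal(rep_only$matrix$fp, 27)
  expect_equal(rep_only$matrix$tn, 379)
  expect_equal(rep_only$specificity$point, 379 / 406, tolerance = 1e-12)
  expect_equal(rep_only$sensitivity$point, 7 / 8)

  vent <- subgroup_metrics(tab, cohort_filter = function(d) d$ventilated)
  expect_equal(vent$n1 + vent$n0, 174)

  # identity filter reproduces the unrestricted report
  idf <- subgroup_metrics(tab, cohort_filter = function(d) rep(TRUE, nrow(d)))
  expect_equal(idf$specificity, whole$specificity)

  expect_error(subgroup_metrics(tab, cohort_filter = function(d) rep(FALSE, nrow(d))),
               "empty cohort")
  none_pos <- subgroup_metrics(tab, positive_filter = function(d) rep(FALSE, nrow(d)))
  expect_equal(none_pos$specificity$point, 1)
  expect_equal(none_pos$sensitivity$point, 0)
})

test_that("2x2 odds ratio and Wald interval", {
  or <- odds_ratio_2x2(2, 1, 1, 2)
  expect_equal(or$estimate, 4)
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$estimate, 1)
  # Wald interval closed form
  expect_equal(or$lower, exp(log(4) - qnorm(0.975) * sqrt(1/2 + 1 + 1 + 1/2)),
               tolerance = 1e-12)
  zero <- odds_ratio_2x2(0, 3, 4, 5)
  expect_true(zero$zero_cell)
  expect_true(is.na(zero$estimate))
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "non-negative")
})
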