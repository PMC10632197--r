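# Patient-level diagnostic accuracy of the screening rule against the
# brain-death reference standard: confusion matrix, the five accuracy metrics
# with confidence intervals (exact, Wilson score, logit-scale predictive
# values), subgroup analyses and the 2x2 odds ratio.

#' Confusion matrix of patient-level screening results
#'
#' @param tp,fp,fn,tn Non-negative integer patient counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix cells must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("screen+", "screen-"),
                              c("brain death", "no brain death")))
  print(m)
  invisible(x)
}

#' Build the confusion matrix from screening results and outcomes
#'
#' Counts patients by screen-positivity (at least one notification during the
#' admission) against the confirmed brain-death outcome.
#'
#' @param screen_positive Character vector of screen-positive patient ids.
#' @param outcomes Data frame with columns `patient_id` and `brain_death`
#'   (logical or 0/1), or a named logical vector.
#' @param cohort Character vector of all patient ids under evaluation;
#'   defaults to all ids in `outcomes`.
#' @return A [confusion_matrix()].
#' @export
build_confusion_matrix <- function(screen_positive, outcomes, cohort = NULL) {
  if (is.data.frame(outcomes)) {
    bd <- as.logical(outcomes$brain_death)
    names(bd) <- as.character(outcomes$patient_id)
  } else {
    bd <- as.logical(outcomes)
  }
  cohort <- as.character(cohort %||% names(bd))
  screen_positive <- unique(as.character(screen_positive))
  if (!all(screen_positive %in% cohort))
    stop("screen-positive patient(s) not in cohort: ",
         paste(setdiff(screen_positive, cohort), collapse = ", "))
  if (!all(cohort %in% names(bd)))
    stop("outcome missing for patient(s): ",
         paste(setdiff(cohort, names(bd)), collapse = ", "))
  bd <- bd[cohort]
  pos <- cohort %in% screen_positive
  confusion_matrix(tp = sum(pos & bd), fp = sum(pos & !bd),
                   fn = sum(!pos & bd), tn = sum(!pos & !bd))
}

.interval <- function(point, lower = NA_real_, upper = NA_real_,
                      method = "none", confidence = 0.95,
                      x = NA_integer_, n = NA_integer_) {
  structure(list(point = point, lower = lower, upper = upper,
                 method = method, confidence = confidence,
                 x = x, n = n),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  if (is.na(x$point)) {
    cat("undefined (zero denominator)\n")
  } else if (x$method == "none") {
    cat(sprintf("%.1f%% (no CI)\n", 100 * x$point))
  } else {
    cat(sprintf("%.1f%% (%.0f%% CI %.1f-%.1f, %s)\n", 100 * x$point,
                100 * x$confidence, 100 * x$lower, 100 * x$upper, x$method))
  }
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion via Beta quantiles;
#' conservative coverage. The lower bound is 0 when `x = 0` and the upper
#' bound 1 when `x = n` (for `x = n` the lower bound has the closed form
#' `(alpha/2)^(1/n)`).
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson_ci(8, 8)  # lower = 0.025^(1/8) = 0.6306
#' @export
clopper_pearson_ci <- function(x, n, confidence = 0.95) {
  .check_xn(x, n, confidence)
  a <- (1 - confidence) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  c(lower = unname(lower), upper = unname(upper))
}

#' Wilson score confidence interval
#'
#' Score-based binomial interval with approximately nominal coverage; bounds
#' always inside \[0, 1\].
#'
#' @inheritParams clopper_pearson_ci
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, confidence = 0.95) {
  .check_xn(x, n, confidence)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

.check_xn <- function(x, n, confidence) {
  if (!is_scalar_number(n) || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (!is_scalar_number(x) || x < 0 || x > n || x != round(x))
    stop("x must be an integer in [0, n]")
  if (!is_scalar_number(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  invisible(TRUE)
}

#' Logit-scale confidence interval for a predictive value
#'
#' Predictive values are prevalence-dependent, so their intervals are built
#' from sensitivity, specificity and prevalence rather than as plain binomial
#' proportions. The point estimate is the Bayes-theorem predictive value at
#' the given prevalence; the interval is a delta-method interval on the logit
#' scale with
#' `Var(logit PPV) = (1-se)/(se*n1) + sp/((1-sp)*n0)` and
#' `Var(logit NPV) = se/((1-se)*n1) + (1-sp)/(sp*n0)`,
#' where `n1`/`n0` are the condition-positive/negative counts. At boundary
#' sensitivity/specificity the variance is undefined and the point estimate
#' is returned without bounds (method `"none"`), mirroring how a perfect
#' predictive value is reported without an interval.
#'
#' @param which `"PPV"` or `"NPV"`.
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @param n1,n0 Condition-positive and condition-negative counts (>= 1).
#' @param prevalence Condition prevalence; defaults to `n1 / (n1 + n0)`.
#' @param confidence Confidence level.
#' @return An `interval_estimate`.
#' @examples
#' predictive_value_ci_logit("PPV", se = 1, sp = 360/406, n1 = 8, n0 = 406)
#' @export
predictive_value_ci_logit <- function(which = c("PPV", "NPV"), se, sp, n1, n0,
                                      prevalence = n1 / (n1 + n0),
                                      confidence = 0.95) {
  which <- match.arg(which)
  if (n1 < 1 || n0 < 1) stop("n1 and n0 must be >= 1")
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            prevalence >= 0, prevalence <= 1)
  p <- prevalence
  point <- if (which == "PPV") {
    den <- se * p + (1 - sp) * (1 - p)
    if (den == 0) NA_real_ else se * p / den
  } else {
    den <- sp * (1 - p) + (1 - se) * p
    if (den == 0) NA_real_ else sp * (1 - p) / den
  }
  variance <- if (which == "PPV") {
    if (se == 0 || sp == 1) Inf
    else (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
  } else {
    if (se == 1 || sp == 0) Inf
    else se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
  }
  if (is.na(point) || !is.finite(variance) || point %in% c(0, 1))
    return(.interval(point, method = "none", confidence = confidence))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  lg <- stats::qlogis(point)
  .interval(point,
            lower = stats::plogis(lg - z * sqrt(variance)),
            upper = stats::plogis(lg + z * sqrt(variance)),
            method = "mercaldo_logit", confidence = confidence)
}

#' Diagnostic accuracy report from a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive value
#' and overall accuracy with confidence intervals. Sensitivity, specificity
#' and accuracy get binomial intervals by `ci_method`; predictive values get
#' logit-scale intervals via [predictive_value_ci_logit()] at the cohort
#' prevalence. A metric whose denominator is zero, or whose interval variance
#' is degenerate, is reported as undefined / without bounds rather than
#' with fabricated ones.
#'
#' @param matrix A [confusion_matrix()].
#' @param ci_method `"clopper_pearson"` (default; matches exact printed
#'   bounds) or `"wilson"`.
#' @param confidence Confidence level.
#' @return Object of class `accuracy_report`: interval estimates for the five
#'   metrics plus the matrix, class sizes `n1`/`n0` and prevalence.
#' @export
diagnostic_metrics <- function(matrix, ci_method = c("clopper_pearson", "wilson"),
                               confidence = 0.95) {
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, clopper_pearson = clopper_pearson_ci, wilson = wilson_ci)
  tp <- matrix$tp; fp <- matrix$fp; fn <- matrix$fn; tn <- matrix$tn
  n1 <- tp + fn; n0 <- tn + fp; n <- n1 + n0
  prop <- function(x, d) {
    if (d == 0) return(.interval(NA_real_, confidence = confidence))
    ci <- ci_fun(x, d, confidence)
    .interval(x / d, ci[["lower"]], ci[["upper"]], ci_method, confidence, x, d)
  }
  se <- if (n1 > 0) tp / n1 else NA_real_
  sp <- if (n0 > 0) tn / n0 else NA_real_
  pv <- function(which, num, den) {
    if (den == 0 || n1 == 0 || n0 == 0)
      return(.interval(if (den > 0) num / den else NA_real_,
                       confidence = confidence))
    est <- predictive_value_ci_logit(which, se, sp, n1, n0,
                                     prevalence = n1 / n, confidence = confidence)
    est$x <- num; est$n <- den
    est
  }
  structure(list(
    sensitivity = prop(tp, n1),
    specificity = prop(tn, n0),
    ppv = pv("PPV", tp, tp + fp),
    npv = pv("NPV", tn, tn + fn),
    accuracy = prop(tp + tn, n),
    matrix = matrix,
    n1 = n1, n0 = n0,
    prevalence = if (n > 0) n1 / n else NA_real_,
    ci_method = ci_method,
    confidence = confidence
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 1, ...) {
  cat(sprintf("Diagnostic accuracy (N = %d, prevalence %.1f%%, %s / logit predictive values)\n",
              x$n1 + x$n0, 100 * x$prevalence, x$ci_method))
  fmt <- function(est, label) {
    if (is.na(est$point)) {
      cat(sprintf("  %-26s undefined (zero denominator)\n", label))
    } else if (est$method == "none") {
      cat(sprintf("  %-26s %s\n", label,
                  format(round_half_up(100 * est$point, digits), nsmall = digits)))
    } else {
      cat(sprintf("  %-26s %s (%s-%s)\n", label,
                  format(round_half_up(100 * est$point, digits), nsmall = digits),
                  format(round_half_up(100 * est$lower, digits), nsmall = digits),
                  format(round_half_up(100 * est$upper, digits), nsmall = digits)))
    }
  }
  cat(sprintf("  %-26s %% (%.0f%% CI)\n", "estimate", 100 * x$confidence))
  fmt(x$sensitivity, "Sensitivity")
  fmt(x$specificity, "Specificity")
  fmt(x$ppv, "Positive predictive value")
  fmt(x$npv, "Negative predictive value")
  fmt(x$accuracy, "Overall accuracy")
  invisible(x)
}

#' Patient-level evaluation table
#'
#' Joins the notification log onto the outcomes table, yielding one row per
#' cohort patient with `screen_positive` (>= 1 notification),
#' `repeat_detected` (>= 2 notifications) and the outcome / covariate columns
#' carried through — the input for [subgroup_metrics()] and the odds-ratio
#' analysis.
#'
#' @param log A `notification_log` from [run_screening()].
#' @param outcomes Data frame with `patient_id`, `brain_death` and optional
#'   covariates (e.g. `ventilated`, `analgosedation`).
#' @return Data frame, one row per patient in `outcomes`.
#' @export
evaluation_table <- function(log, outcomes) {
  counts <- table(log$patient_id)
  df <- outcomes
  df$patient_id <- as.character(df$patient_id)
  df$brain_death <- as.logical(df$brain_death)
  nn <- as.integer(counts[df$patient_id])
  nn[is.na(nn)] <- 0L
  df$n_notifications <- nn
  df$screen_positive <- nn >= 1L
  df$repeat_detected <- nn >= 2L
  df
}

#' Diagnostic metrics on a subgroup or a redefined positivity
#'
#' Two distinct restriction semantics are supported, as both appear in
#' screening evaluations. A *cohort filter* restricts the evaluation to a
#' patient subgroup (e.g. mechanically ventilated patients), recomputing all
#' metrics within it. A *positivity filter* keeps the full cohort but narrows
#' what counts as screen-positive (e.g. only patients detected repeatedly),
#' so filtered-out positives become test-negatives.
#'
#' @param eval_table Patient-level table from [evaluation_table()] (columns
#'   `screen_positive`, `brain_death`, plus covariates).
#' @param cohort_filter Optional predicate: function of the table returning a
#'   logical row mask defining the subgroup cohort.
#' @param positive_filter Optional predicate: function of the table returning
#'   a logical row mask; positivity becomes `screen_positive & mask`.
#' @param ci_method,confidence Passed to [diagnostic_metrics()].
#' @return An `accuracy_report` for the redefined matrix.
#' @export
subgroup_metrics <- function(eval_table, cohort_filter = NULL,
                             positive_filter = NULL,
                             ci_method = c("clopper_pearson", "wilson"),
                             confidence = 0.95) {
  df <- eval_table
  if (!is.null(cohort_filter)) {
    keep <- cohort_filter(df)
    df <- df[!is.na(keep) & keep, , drop = FALSE]
  }
  if (!nrow(df)) stop("subgroup filter leaves an empty cohort")
  pos <- df$screen_positive
  if (!is.null(positive_filter)) pos <- pos & positive_filter(df)
  m <- confusion_matrix(tp = sum(pos & df$brain_death),
                        fp = sum(pos & !df$brain_death),
                        fn = sum(!pos & df$brain_death),
                        tn = sum(!pos & !df$brain_death))
  diagnostic_metrics(m, ci_method = ci_method, confidence = confidence)
}

#' 2x2 odds ratio with Wald confidence interval
#'
#' Cross-tabulates a binary exposure against a binary outcome (e.g. continuous
#' analgosedation against screen-positivity). With a single binary predictor
#' this is identical to the odds ratio from a bivariate logistic regression.
#' With any zero cell the odds ratio is reported as undefined (no continuity
#' correction is applied).
#'
#' @param exposed_pos,unexposed_pos Outcome-positive counts by exposure.
#' @param exposed_neg,unexposed_neg Outcome-negative counts by exposure.
#' @param confidence Confidence level.
#' @return Object of class `odds_ratio`: `estimate`, `lower`, `upper`,
#'   `zero_cell`, `confidence`.
#' @examples
#' odds_ratio_2x2(48, 6, 204, 156)  # OR 6.1 (2.6-14.7)
#' @export
odds_ratio_2x2 <- function(exposed_pos, unexposed_pos, exposed_neg, unexposed_neg,
                           confidence = 0.95) {
  cells <- c(a = exposed_pos, b = unexposed_pos, c = exposed_neg, d = unexposed_neg)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    return(structure(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                          zero_cell = TRUE, cells = cells, confidence = confidence),
                     class = "odds_ratio"))
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se_log <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  structure(list(estimate = or,
                 lower = exp(log(or) - z * se_log),
                 upper = exp(log(or) + z * se_log),
                 zero_cell = FALSE, cells = cells, confidence = confidence),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  if (x$zero_cell) {
    cat("OR undefined (zero cell in 2x2 table)\n")
  } else {
    cat(sprintf("OR %.1f (%.0f%% CI %.1f-%.1f)\n", x$estimate,
                100 * x$confidence, x$lower, x$upper))
  }
  invisible(x)
}
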