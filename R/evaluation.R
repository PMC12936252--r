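# Evaluation of predicted resorption grades against clinical ground truth:
# 4-class confusion matrix, one-vs-rest per-grade metrics and ROC-AUC,
# Grade-0-referenced measurement error, two-way random-effects ICC, and the
# exact binomial power analysis used for sample-size planning.

GRADE_LEVELS <- 0:3

#' Confusion matrix for grade predictions
#'
#' @param truth,pred Equal-length vectors of grades 0-3; rows of the result
#'   are true grades, columns predicted grades.
#' @return An integer 4x4 matrix of class `table`-like counts.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("pairing error: truth and pred differ in length", call. = FALSE)
  }
  if (any(!truth %in% GRADE_LEVELS) || any(!pred %in% GRADE_LEVELS)) {
    stop("grades must be integers 0-3", call. = FALSE)
  }
  m <- table(factor(truth, levels = GRADE_LEVELS),
             factor(pred, levels = GRADE_LEVELS))
  m <- unclass(m)
  dimnames(m) <- list(truth = GRADE_LEVELS, pred = GRADE_LEVELS)
  storage.mode(m) <- "integer"
  m
}

#' One-vs-rest counts for one positive grade
#'
#' Collapses a 4x4 confusion matrix into binary TP/FP/FN/TN counts with the
#' given grade as the positive class and the other three pooled as negative.
#'
#' @param m 4x4 confusion matrix, rows = truth, columns = prediction.
#' @param positive_grade Grade 0-3 treated as positive.
#' @return List with `tp`, `fp`, `fn`, `tn`; their sum equals `sum(m)`.
#' @export
ovr_counts <- function(m, positive_grade) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  g <- match(positive_grade, GRADE_LEVELS[seq_len(nrow(m))])
  if (is.na(g)) stop("positive_grade not a grade of this matrix",
                     call. = FALSE)
  tp <- m[g, g]
  fn <- sum(m[g, ]) - tp
  fp <- sum(m[, g]) - tp
  tn <- sum(m) - tp - fn - fp
  list(tp = as.integer(tp), fp = as.integer(fp),
       fn = as.integer(fn), tn = as.integer(tn))
}

safe_div <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Binary classification metrics from one-vs-rest counts
#'
#' Per-class "accuracy" is one-vs-rest binary accuracy `(tp+tn)/n`, which is
#' why it can differ from recall for the same grade. Ratios with a zero
#' denominator are reported as 0 and flagged in the `degenerate` field.
#'
#' @param counts List with `tp`, `fp`, `fn`, `tn` (see [ovr_counts()]).
#' @return List of `accuracy`, `precision`, `recall`, `specificity`, `f1`,
#'   `support` (true positives + false negatives) and a `degenerate` flag.
#' @export
class_metrics <- function(counts) {
  with(counts, {
    n <- tp + fp + fn + tn
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    specificity <- safe_div(tn, tn + fp)
    f1 <- safe_div(2 * precision * recall, precision + recall)
    degenerate <- any(vapply(list(precision, recall, specificity, f1),
                             function(x) isTRUE(attr(x, "degenerate")),
                             logical(1)))
    list(accuracy = (tp + tn) / n, precision = as.numeric(precision),
         recall = as.numeric(recall), specificity = as.numeric(specificity),
         f1 = as.numeric(f1), support = tp + fn, degenerate = degenerate)
  })
}

#' Support-weighted average of per-class metrics
#'
#' Averages each metric over classes with weights proportional to the true
#' class supports. With these weights the weighted recall equals the overall
#' multiclass accuracy (trace / n).
#'
#' @param per_class List of [class_metrics()] results.
#' @return List with the five weighted metrics and the total support.
#' @export
weighted_summary <- function(per_class) {
  supports <- vapply(per_class, `[[`, numeric(1), "support")
  total <- sum(supports)
  if (total == 0) stop("weighted_summary: total support is zero",
                       call. = FALSE)
  w <- supports / total
  avg <- function(field) {
    sum(w * vapply(per_class, `[[`, numeric(1), field))
  }
  list(accuracy = avg("accuracy"), precision = avg("precision"),
       recall = avg("recall"), specificity = avg("specificity"),
       f1 = avg("f1"), support = total)
}

#' Single-operating-point (hard) one-vs-rest ROC
#'
#' A classifier that outputs labels, not scores, yields exactly one
#' (FPR, TPR) operating point per grade; the ROC "curve" is the polygon
#' (0,0) -> (FPR, TPR) -> (1,1) and its area is `(1 + TPR - FPR) / 2`, which
#' equals balanced accuracy `(recall + specificity) / 2`.
#'
#' @param counts One-vs-rest counts, see [ovr_counts()].
#' @return List with `tpr`, `fpr` and `auc`.
#' @export
hard_ovr_auc <- function(counts) {
  with(counts, {
    if (tp + fn < 1 || fp + tn < 1) {
      stop("hard_ovr_auc: positive and negative classes must be non-empty",
           call. = FALSE)
    }
    tpr <- tp / (tp + fn)
    fpr <- fp / (fp + tn)
    list(tpr = tpr, fpr = fpr, auc = (1 + tpr - fpr) / 2)
  })
}

#' Ordinal-score one-vs-rest ROC-AUC
#'
#' Treats an ordinal prediction (the predicted grade, or the continuous
#' resorption percentage) as a ranking score and computes the tie-corrected
#' Mann-Whitney AUC: the probability that a random positive outranks a
#' random negative, ties counting one half. Provided as a non-default
#' alternative to [hard_ovr_auc()] for classifiers that expose more than a
#' label.
#'
#' @param truth_binary Logical (or 0/1) vector marking positives.
#' @param scores Numeric ordinal scores, higher = more positive.
#' @return List with `auc` and the ROC step curve (`fpr`, `tpr` vectors over
#'   descending score thresholds).
#' @export
ordinal_ovr_auc <- function(truth_binary, scores) {
  truth_binary <- as.logical(truth_binary)
  if (length(truth_binary) != length(scores)) {
    stop("pairing error: truth and scores differ in length", call. = FALSE)
  }
  n_pos <- sum(truth_binary)
  n_neg <- sum(!truth_binary)
  if (n_pos == 0 || n_neg == 0) {
    stop("ordinal_ovr_auc: both classes must be non-empty", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[truth_binary]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[truth_binary] >= t),
                numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!truth_binary] >= t),
                numeric(1))
  list(auc = auc, fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Grade-0-referenced measurement error
#'
#' Teeth clinically graded 0 (no detectable resorption) are assumed to have
#' a true resorption of 0%, so their predicted percentages estimate the
#' intrinsic measurement error of the pipeline. Reports the mean absolute
#' predicted percentage and the standard deviation (n-1 denominator) of the
#' signed predictions over that reference set.
#'
#' @param measurements Measurement table with `patient_id`, `tooth` and
#'   `resorption_percent` columns.
#' @param truth Ground-truth table with `patient_id`, `tooth` and
#'   `true_grade` columns.
#' @return List with `mean_abs_error_percent`, `sd_percent` and
#'   `n_reference_teeth`.
#' @export
grade0_error <- function(measurements, truth) {
  merged <- merge(measurements, truth[, c("patient_id", "tooth",
                                          "true_grade")],
                  by = c("patient_id", "tooth"))
  ref <- merged[merged$true_grade == 0 & is.finite(merged$resorption_percent), ]
  if (nrow(ref) < 1) {
    stop("grade0_error: no Grade-0 reference teeth available", call. = FALSE)
  }
  list(mean_abs_error_percent = mean(abs(ref$resorption_percent)),
       sd_percent = if (nrow(ref) > 1) stats::sd(ref$resorption_percent)
                    else 0,
       n_reference_teeth = nrow(ref))
}

#' Intraclass correlation for repeated gradings
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1) in the Shrout-Fleiss scheme), computed from the two-way ANOVA
#' mean squares of an n-subject by k-session rating table. Absolute
#' agreement penalizes systematic offsets between sessions, which is the
#' appropriate form for test-retest consistency of consensus gradings.
#'
#' @param ratings Numeric matrix or data.frame, one row per subject, one
#'   column per rating session (k >= 2, n >= 3).
#' @return List with `icc`, `model_label`, the mean squares, and an
#'   `undefined` flag set when between-subject variance is zero.
#' @export
icc_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  if (!is.numeric(x) || nrow(x) < 3 || ncol(x) < 2) {
    stop("icc_agreement: need a numeric table, >= 3 subjects, >= 2 sessions",
         call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0 && msc == 0)) {
    return(list(icc = NA_real_,
                model_label = "two-way random, absolute agreement, single",
                msr = msr, msc = msc, mse = mse, undefined = TRUE))
  }
  list(icc = (msr - mse) / denom,
       model_label = "two-way random, absolute agreement, single",
       msr = msr, msc = msc, mse = mse, undefined = FALSE)
}

#' Sample size by exact binomial power analysis
#'
#' One-tailed exact binomial test of H0: p = `p0` against p = `p0 + g`.
#' For each candidate n, the critical count k is the smallest integer with
#' P(X >= k | n, p0) <= alpha; the scan returns the smallest n whose exact
#' power P(X >= k | n, p0 + g) reaches the target (exact power is sawtoothed
#' in n, so this is the first qualifying n, not the start of an all-qualifying
#' tail). This is the convention of standard power-analysis software for the
#' exact binomial test.
#'
#' @param p0 Null proportion (e.g. 0.25, chance level of a 4-class task).
#' @param g Effect size: difference between the alternative and `p0`.
#' @param alpha One-tailed significance level.
#' @param target_power Required power.
#' @param n_max Scan cap.
#' @return List with `n`, critical count `k`, `achieved_alpha` and
#'   `achieved_power`.
#' @examples
#' sample_size_exact_binomial(0.25, 0.05, 0.05, 0.80)$n  # 494
#' @export
sample_size_exact_binomial <- function(p0, g, alpha = 0.05,
                                       target_power = 0.80, n_max = 1e6) {
  if (!(p0 > 0 && p0 + g < 1 && g > 0)) {
    stop("need 0 < p0 < p0 + g < 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1 && target_power > 0 && target_power < 1)) {
    stop("alpha and target_power must be in (0, 1)", call. = FALSE)
  }
  p1 <- p0 + g
  for (n in seq_len(n_max)) {
    # smallest k with P(X >= k | n, p0) <= alpha
    k <- stats::qbinom(1 - alpha, n, p0) + 1
    if (k > n) next  # even n successes are not significant
    achieved_alpha <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    power <- stats::pbinom(k - 1, n, p1, lower.tail = FALSE)
    if (power >= target_power) {
      return(list(n = as.integer(n), k = as.integer(k),
                  achieved_alpha = achieved_alpha, achieved_power = power))
    }
  }
  stop(sprintf("no n <= %g reaches power %g (p0 = %g, g = %g, alpha = %g)",
               n_max, target_power, p0, g, alpha), call. = FALSE)
}

#' Total sample size including a training share
#'
#' Smallest integer total t with `t * train_fraction >= n_required`, i.e.
#' the total needed so that the training share alone meets the requirement.
#'
#' @param n_required Required sample size (e.g. from
#'   [sample_size_exact_binomial()]).
#' @param train_fraction Fraction allocated to training, in (0, 1).
#' @return Integer total.
#' @examples
#' total_with_split(494, 0.8)  # 618
#' @export
total_with_split <- function(n_required, train_fraction) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_required < 1) stop("n_required must be >= 1", call. = FALSE)
  as.integer(ceiling(n_required / train_fraction))
}

#' Full grade evaluation report
#'
#' Builds the confusion matrix and, per grade, one-vs-rest counts, metrics
#' and the hard ROC point; adds the support-weighted summary, the overall
#' multiclass accuracy, and (optionally) ordinal AUCs when scores are given.
#'
#' @param truth,pred Grade vectors 0-3.
#' @param scores Optional numeric ordinal scores (e.g. predicted resorption
#'   percentages) for the ordinal AUC mode.
#' @return List: `confusion`, `per_class` (data.frame, one row per grade),
#'   `weighted`, `overall_accuracy`, `n`.
#' @export
evaluate_grades <- function(truth, pred, scores = NULL) {
  m <- confusion(truth, pred)
  per <- lapply(GRADE_LEVELS, function(g) {
    cnt <- ovr_counts(m, g)
    met <- class_metrics(cnt)
    roc <- if (cnt$tp + cnt$fn >= 1 && cnt$fp + cnt$tn >= 1) {
      hard_ovr_auc(cnt)
    } else list(tpr = NA_real_, fpr = NA_real_, auc = NA_real_)
    ord_auc <- if (!is.null(scores) && met$support > 0 &&
                   met$support < sum(m)) {
      ordinal_ovr_auc(truth == g, scores)$auc
    } else NA_real_
    data.frame(grade = g, support = met$support, accuracy = met$accuracy,
               precision = met$precision, recall = met$recall,
               specificity = met$specificity, f1 = met$f1,
               tpr = roc$tpr, fpr = roc$fpr, auc_hard = roc$auc,
               auc_ordinal = ord_auc)
  })
  per_class <- do.call(rbind, per)
  metrics_list <- lapply(GRADE_LEVELS, function(g) {
    class_metrics(ovr_counts(m, g))
  })
  list(confusion = m, per_class = per_class,
       weighted = weighted_summary(metrics_list),
       overall_accuracy = sum(diag(m)) / sum(m), n = sum(m))
}
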