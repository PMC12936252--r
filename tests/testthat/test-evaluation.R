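# Toy 4x4 confusion matrix used across several checks (rows = truth).
toy_matrix <- function() {
  m <- matrix(c(5, 1, 0, 0,
                1, 3, 1, 0,
                0, 1, 4, 1,
                0, 0, 1, 6), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(truth = 0:3, pred = 0:3)
  storage.mode(m) <- "integer"
  m
}

# Expand a confusion matrix back into truth/prediction vectors.
vectors_from_matrix <- function(m) {
  truth <- integer(0); pred <- integer(0)
  for (i in 1:4) for (j in 1:4) {
    truth <- c(truth, rep(i - 1L, m[i, j]))
    pred <- c(pred, rep(j - 1L, m[i, j]))
  }
  list(truth = truth, pred = pred)
}

test_that("confusion matrices count truth x prediction pairs", {
  expect_equal(confusion(rep(0:3, each = 3), rep(0:3, each = 3)),
               confusion(rep(0:3, each = 3), rep(0:3, each = 3)))
  perfect <- confusion(c(0, 1, 2, 3, 0, 1, 2, 3, 1, 2),
                       c(0, 1, 2, 3, 0, 1, 2, 3, 1, 2))
  expect_equal(sum(diag(perfect)), 10)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  swapped <- confusion(c(0, 1), c(1, 0))
  expect_equal(swapped[1, 2], 1L)
  expect_equal(swapped[2, 1], 1L)
  set.seed(8)
  t <- sample(0:3, 1000, replace = TRUE)
  p <- sample(0:3, 1000, replace = TRUE)
  expect_equal(sum(confusion(t, p)), 1000)
  expect_error(confusion(0:2, 0:3), "pairing error")
  expect_error(confusion(c(0, 4), c(0, 1)), "0-3")
  v <- vectors_from_matrix(toy_matrix())
  expect_equal(confusion(v$truth, v$pred), toy_matrix())
})

test_that("one-vs-rest counts collapse the matrix correctly", {
  m <- toy_matrix()
  c0 <- ovr_counts(m, 0)
  expect_equal(c0, list(tp = 5L, fp = 1L, fn = 1L, tn = 17L))
  expect_equal(with(c0, tp + fp + fn + tn), sum(m))
  diag_m <- diag(c(3L, 4L, 5L, 6L))
  for (g in 0:3) {
    cg <- ovr_counts(diag_m, g)
    expect_equal(cg$fp, 0L)
    expect_equal(cg$fn, 0L)
  }
  tps <- vapply(0:3, function(g) ovr_counts(m, g)$tp, integer(1))
  expect_equal(sum(tps), sum(diag(m)))
  fps <- vapply(0:3, function(g) ovr_counts(m, g)$fp, integer(1))
  fns <- vapply(0:3, function(g) ovr_counts(m, g)$fn, integer(1))
  expect_equal(sum(fps), sum(m) - sum(diag(m)))
  expect_equal(sum(fns), sum(m) - sum(diag(m)))
})

test_that("class metrics match the binary definitions", {
  met <- class_metrics(list(tp = 5L, fp = 1L, fn = 1L, tn = 17L))
  expect_equal(met$precision, 5 / 6)
  expect_equal(met$recall, 5 / 6)
  expect_equal(met$specificity, 17 / 18)
  expect_equal(met$accuracy, 22 / 24)
  expect_equal(met$f1, 5 / 6)  # precision = recall here
  expect_false(met$degenerate)
  perfect <- class_metrics(list(tp = 10L, fp = 0L, fn = 0L, tn = 30L))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1")]) == 1))
  degen <- class_metrics(list(tp = 0L, fp = 0L, fn = 2L, tn = 20L))
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
})

test_that("support-weighted recall equals overall multiclass accuracy", {
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(rpois(16, 5), 4)
    if (any(rowSums(m) == 0)) next
    per <- lapply(0:3, function(g) class_metrics(ovr_counts(m, g)))
    w <- weighted_summary(per)
    expect_equal(w$recall, sum(diag(m)) / sum(m), tolerance = 1e-12)
  }
  same <- replicate(3, list(accuracy = 0.9, precision = 0.8, recall = 0.7,
                            specificity = 0.95, f1 = 0.746, support = 5,
                            degenerate = FALSE), simplify = FALSE)
  expect_equal(weighted_summary(same)$precision, 0.8)
  two <- list(list(accuracy = 1, precision = 1, recall = 1, specificity = 1,
                   f1 = 1, support = 3),
              list(accuracy = 0, precision = 0, recall = 0, specificity = 0,
                   f1 = 0, support = 1))
  expect_equal(weighted_summary(two)$recall, 0.75)
})

test_that("hard one-vs-rest AUC is the trapezoid through the single point", {
  pt <- hard_ovr_auc(list(tp = 85L, fn = 15L, fp = 6L, tn = 94L))
  expect_equal(pt$auc, 0.895)
  expect_equal(hard_ovr_auc(list(tp = 10L, fn = 0L, fp = 0L, tn = 10L))$auc,
               1)
  chance <- hard_ovr_auc(list(tp = 5L, fn = 5L, fp = 50L, tn = 50L))
  expect_equal(chance$auc, 0.5)
  expect_error(hard_ovr_auc(list(tp = 0L, fn = 0L, fp = 1L, tn = 1L)),
               "non-empty")
})

test_that("hard AUC equals balanced accuracy on arbitrary matrices", {
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(rpois(16, 4) + 1, 4)
    for (g in 0:3) {
      cnt <- ovr_counts(m, g)
      met <- class_metrics(cnt)
      expect_equal(hard_ovr_auc(cnt)$auc,
                   (met$recall + met$specificity) / 2, tolerance = 1e-12)
    }
  }
})

pair_counting_auc <- function(truth, scores) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("ordinal AUC equals brute-force pair counting with ties at 1/2", {
  expect_equal(ordinal_ovr_auc(c(1, 1, 0, 0), c(4, 3, 2, 1))$auc, 1)
  expect_equal(ordinal_ovr_auc(c(1, 1, 0, 0), c(2, 2, 2, 2))$auc, 0.5)
  set.seed(77)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0 || sum(truth) == n) next
    scores <- sample(0:3, n, replace = TRUE)  # heavy ties, like grades
    expect_equal(ordinal_ovr_auc(truth, scores)$auc,
                 pair_counting_auc(truth, scores), tolerance = 1e-12)
  }
  expect_error(ordinal_ovr_auc(rep(1, 5), 1:5), "non-empty")
})

test_that("grade-0 reference error summarizes signed prediction errors", {
  meas <- data.frame(patient_id = "p1", tooth = c(12, 11, 21),
                     resorption_percent = c(2, -1, 3))
  truth <- data.frame(patient_id = "p1", tooth = c(12, 11, 21),
                      true_grade = c(0, 0, 0))
  e <- grade0_error(meas, truth)
  expect_equal(e$mean_abs_error_percent, 2)
  expect_equal(e$sd_percent, sd(c(2, -1, 3)))
  expect_equal(round(e$sd_percent, 4), 2.0817)
  expect_equal(e$n_reference_teeth, 3)
  zero <- grade0_error(transform(meas, resorption_percent = 0), truth)
  expect_equal(zero$mean_abs_error_percent, 0)
  expect_equal(zero$sd_percent, 0)
  truth$true_grade <- c(1, 2, 3)
  expect_error(grade0_error(meas, truth), "no Grade-0")
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  x <- cbind(s1 = c(9, 6.5, 8, 7.5, 10, 6),
             s2 = c(8.5, 7, 8, 7, 9.5, 5))
  # independent oracle: mean squares from a two-way fixed-effects fit
  long <- data.frame(y = c(x[, 1], x[, 2]),
                     subject = factor(rep(1:6, 2)),
                     session = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subject + session, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  res <- icc_agreement(x)
  expect_equal(res$icc, oracle, tolerance = 1e-9)
  expect_match(res$model_label, "absolute agreement")
})

test_that("ICC is exactly 1 on duplicated columns and penalizes offsets", {
  x <- c(3, 7, 5, 9, 4, 6)
  expect_equal(icc_agreement(cbind(x, x))$icc, 1)
  shifted <- icc_agreement(cbind(x, x + 2))
  expect_lt(shifted$icc, 1)
  expect_gt(shifted$icc, 0)  # ordering preserved, only offset penalized
  # relabeling subjects leaves ICC unchanged
  perm <- sample(seq_along(x))
  expect_equal(icc_agreement(cbind(x, x + 2)[perm, ])$icc, shifted$icc)
  flat <- icc_agreement(cbind(rep(2, 4), rep(2, 4)))
  expect_true(flat$undefined)
})

test_that("exact binomial sample size follows the critical-value scan", {
  # brute-force oracle over tiny n for a huge effect
  oracle_n <- NA
  for (n in 1:10) {
    tails0 <- rev(cumsum(rev(dbinom(0:n, n, 0.25))))
    k <- which(tails0 <= 0.05)[1] - 1  # smallest k with P(X>=k|p0)<=alpha
    if (is.na(k) || k > n) next
    power <- sum(dbinom(k:n, n, 0.99))
    if (power >= 0.80) { oracle_n <- n; break }
  }
  res <- sample_size_exact_binomial(0.25, 0.74, 0.05, 0.80)
  expect_equal(res$n, oracle_n)
  expect_equal(res$n, 3L)
  expect_equal(res$k, 3L)
  expect_equal(res$achieved_alpha, 0.25^3, tolerance = 1e-12)
  expect_equal(res$achieved_power, 0.99^3, tolerance = 1e-12)
})

test_that("returned n meets the power target at the achieved alpha", {
  for (g in c(0.1, 0.2, 0.3)) {
    res <- sample_size_exact_binomial(0.25, g, 0.05, 0.80)
    expect_lte(res$achieved_alpha, 0.05)
    expect_gte(res$achieved_power, 0.80)
    # direct tail-sum re-check
    expect_equal(res$achieved_power,
                 sum(dbinom(res$k:res$n, res$n, 0.25 + g)), tolerance = 1e-12)
  }
  expect_error(sample_size_exact_binomial(0.5, 0.6), "p0")
})

test_that("train-share totals take the ceiling of the quotient", {
  expect_equal(total_with_split(100, 0.5), 200L)
  expect_equal(total_with_split(1, 0.8), 2L)
  expect_equal(total_with_split(101, 0.5), 202L)
  expect_error(total_with_split(100, 1), "train_fraction")
})

test_that("evaluate_grades assembles a coherent report", {
  v <- vectors_from_matrix(toy_matrix())
  rep <- evaluate_grades(v$truth, v$pred)
  expect_equal(rep$confusion, toy_matrix())
  expect_equal(rep$overall_accuracy, 18 / 24)
  row0 <- rep$per_class[rep$per_class$grade == 0, ]
  expect_equal(row0$precision, 5 / 6)
  expect_equal(row0$auc_hard, (5 / 6 + 17 / 18) / 2)
  expect_equal(rep$weighted$recall, 18 / 24)
  perfect <- evaluate_grades(v$truth, v$truth)
  expect_true(all(perfect$per_class$auc_hard == 1))
  expect_equal(perfect$overall_accuracy, 1)
})
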