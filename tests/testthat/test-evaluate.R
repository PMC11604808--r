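test_that("combine_scores is the fixed pre-minus-inter contrast", {
  expect_equal(combine_scores(1, 0), 1)
  expect_equal(combine_scores(0.5, 0.5), 0)
  expect_error(combine_scores(c(1, 0), 1), "same length")
  # when inter = 1 - pre, the combined score is a monotone transform of
  # pre alone, so both induce the same ROC
  set.seed(4)
  pre <- runif(50)
  lab <- runif(50) < pre
  r1 <- roc_auc(combine_scores(pre, 1 - pre), lab)
  r2 <- roc_auc(pre, lab)
  expect_equal(r1$auc, r2$auc)
})

test_that("trapezoidal AUC equals brute-force pair counting, with ties", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:300, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
  }
  # endpoints and degenerate cases
  r <- roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC curve is monotone and matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(200) + rep(c(0.8, 0), each = 100)
  labels <- rep(c(TRUE, FALSE), each = 100)
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  pr <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("Hanley-McNeil interval matches the closed form", {
  ci <- hanley_mcneil_ci(0.5, 1, 1)
  expect_equal(ci$se, 0.5, tolerance = 1e-12)   # Q1 = Q2 = 1/3 exactly
  # independent re-derivation, written as the variance of the
  # Mann-Whitney kernel
  hm_oracle <- function(A, m, n) {
    q1 <- A / (2 - A); q2 <- 2 * A * A / (1 + A)
    sqrt((A - A^2 + (m - 1) * (q1 - A^2) + (n - 1) * (q2 - A^2)) / (m * n))
  }
  ci2 <- hanley_mcneil_ci(0.8, 50, 100)
  expect_equal(ci2$se, hm_oracle(0.8, 50, 100), tolerance = 1e-10)
  expect_equal(ci2$half_width, qnorm(0.975) * ci2$se, tolerance = 1e-10)
  # interval symmetric around the AUC; width shrinks with n
  widths <- vapply(c(10, 40, 160, 640),
                   function(n) hanley_mcneil_ci(0.7, n, n)$half_width, 0)
  expect_true(all(diff(widths) < 0))
  expect_error(hanley_mcneil_ci(1.2, 5, 5), "\\[0, 1\\]")
})

test_that("Hanley-McNeil width agrees with a stratified bootstrap", {
  set.seed(21)
  n <- 200
  pos <- rnorm(n, 1); neg <- rnorm(n, 0)
  scores <- c(pos, neg)
  labels <- rep(c(TRUE, FALSE), each = n)
  a <- pairwise_auc(scores, labels)
  ci <- hanley_mcneil_ci(a, n, n)
  boots <- replicate(2000, {
    bs <- c(sample(pos, n, TRUE), sample(neg, n, TRUE))
    r <- rank(bs)
    (sum(r[1:n]) - n * (n + 1) / 2) / (n * n)   # Mann-Whitney AUC
  })
  expect_equal(ci$se, sd(boots), tolerance = 0.15)
})

test_that("significance rules follow the interval-overlap convention", {
  mk <- function(lo, hi) structure(
    list(auc = (lo + hi) / 2, half_width = (hi - lo) / 2, lower = lo,
         upper = hi, n_pos = 10, n_neg = 10, level = 0.95),
    class = "auc_ci")
  expect_true(compare_aucs(mk(0.6, 0.7), mk(0.75, 0.85)))
  expect_false(compare_aucs(mk(0.6, 0.76), mk(0.75, 0.85)))
  expect_false(vs_random(mk(0.49, 0.61)))     # 0.55 +/- 0.06
  expect_true(vs_random(mk(0.52, 0.6)))
})

test_that("operating points are monotone and match exhaustive search", {
  set.seed(3)
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.55, 0.5, 0.3, 0.2, 0.15, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r <- roc_auc(scores, labels)
  op <- operating_points(r)
  expect_true(all(diff(op$sensitivity) >= 0))  # sweep goes low threshold last
  expect_true(all(diff(op$time_in_high) >= 0))
  # extremes: threshold above all -> (0,0); below all -> (1,1)
  expect_equal(op$sensitivity[1], 0); expect_equal(op$time_in_high[1], 0)
  expect_equal(op$sensitivity[nrow(op)], 1)
  expect_equal(op$time_in_high[nrow(op)], 1)
  # match_point equals exhaustive minimization
  for (target in c(0.2, 0.5, 0.8)) {
    got <- match_point(r, target_sensitivity = target)
    d <- abs(op$sensitivity - target)
    expect_equal(abs(got$sensitivity - target), min(d))
    cand <- op[d == min(d), ]
    expect_equal(got$time_in_high, min(cand$time_in_high))
  }
  got <- match_point(r, target_time_in_high = 0.35)
  expect_equal(abs(got$time_in_high - 0.35),
               min(abs(op$time_in_high - 0.35)))
  expect_error(match_point(r), "exactly one")
})

test_that("confusion matrix, baseline and margins behave", {
  # identity predictions
  cm <- confusion_and_baseline(rep(0:3, 25), rep(0:3, 25), 4)
  expect_equal(cm$accuracy, 1)
  expect_equal(unname(diag(cm$counts)), rep(25L, 4))
  expect_true(all(abs(rowSums(cm$normalized) - 1) < 1e-12))
  # the time-matched random baseline equals the selection proportion
  pred <- c(rep(0, 21), rep(1, 979))
  lab <- rep(0:1, 500)
  cm2 <- confusion_and_baseline(pred, lab, 2)
  expect_equal(unname(cm2$baseline[1]), 0.021)
  # uniform random predictions give baseline sensitivity ~ 1/L
  set.seed(9)
  L <- 5; n <- 20000
  cm3 <- confusion_and_baseline(sample(0:(L - 1), n, TRUE),
                                sample(0:(L - 1), n, TRUE), L)
  expect_true(all(abs(cm3$baseline - 1 / L) < 0.02))
  expect_true(all(abs(cm3$sensitivity - 1 / L) < 0.03))
  expect_equal(sum(cm3$counts), n)
})
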