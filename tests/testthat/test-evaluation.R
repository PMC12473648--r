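test_that("confusion counts exactly", {
  truth <- c(1, 1, 0, 0, 1)
  pred <- c(1, 0, 0, 1, 1)
  cc <- confusion(truth, pred)
  expect_identical(unclass(cc)[c("tp", "fn", "tn", "fp")],
                   list(tp = 2L, fn = 1L, tn = 1L, fp = 1L))

  perfect <- confusion(truth, truth)
  expect_identical(c(perfect$fp, perfect$fn), c(0L, 0L))
  inverted <- confusion(truth, 1 - truth)
  expect_identical(c(inverted$tp, inverted$tn), c(0L, 0L))

  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("metric formulas reproduce the printed definitions", {
  m <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(unclass(m)), c(accuracy = 1, sensitivity = 1,
                                     specificity = 1, precision = 1, f1 = 1))

  # hand-computed case tp=2, fn=1, tn=1, fp=1
  m2 <- classification_metrics(list(tp = 2, fp = 1, tn = 1, fn = 1))
  expect_equal(m2$accuracy, 0.6)
  expect_equal(m2$sensitivity, 2 / 3)
  expect_equal(m2$specificity, 0.5)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$f1, 2 / 3)

  expect_equal(classification_metrics(list(tp = 3, fp = 0, tn = 2, fn = 2))$precision, 1)

  # undefined ratios surface as NaN with a warning, never silent zeros
  w <- capture_warnings(m3 <- classification_metrics(list(tp = 0, fp = 0,
                                                          tn = 4, fn = 0)))
  expect_true(any(grepl("precision", w)))
  expect_true(is.nan(m3$precision))
  expect_true(is.nan(m3$sensitivity))
  expect_equal(m3$specificity, 1)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(31)
  for (i in 1:25) {
    counts <- list(tp = sample(1:40, 1), fp = sample(1:40, 1),
                   tn = sample(1:40, 1), fn = sample(1:40, 1))
    m <- classification_metrics(counts)
    P <- counts$tp + counts$fn; N <- counts$tn + counts$fp
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$sensitivity))
  }
})

test_that("ROC/AUC: separating, symmetric and constant scores", {
  truth <- rep(c(1, 0), each = 10)
  scores <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  r <- roc_and_auc(truth, scores)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$roc_points$fpr) >= 0))   # monotone staircase
  expect_true(all(diff(r$roc_points$tpr) >= 0))

  r_rev <- roc_and_auc(truth, 1 - scores)
  expect_equal(r_rev$auc, 1 - r$auc)

  expect_equal(roc_and_auc(truth, rep(0.5, 20))$auc, 0.5)
  expect_error(roc_and_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  brute_auc <- function(truth, scores) {
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (i in 1:5) {
    n <- sample(c(50, 120, 200), 1)
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0 || sum(truth) == n) next
    scores <- round(runif(n), 2)  # duplicates exercise tie handling
    expect_equal(roc_and_auc(truth, scores)$auc, brute_auc(truth, scores),
                 tolerance = 1e-10)
  }
})

test_that("label-independent scores give chance AUC", {
  set.seed(123)
  truth <- rbinom(200, 1, 0.5)
  scores <- runif(200)
  auc <- roc_and_auc(truth, scores)$auc
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)
})

test_that("evaluation_report composes counts, metrics, ROC and percent format", {
  set.seed(7)
  truth <- rbinom(60, 1, 0.5)
  scores <- ifelse(truth == 1, runif(60, 0.3, 1), runif(60, 0, 0.7))
  rep_ <- evaluation_report(truth, scores, threshold = 0.5)
  ref <- classification_metrics(confusion(truth, scores >= 0.5))
  expect_equal(rep_$metrics, ref)
  expect_match(rep_$percent$accuracy, "^[0-9]+\\.[0-9]%$")
  expect_equal(format_percent(0.977), "97.7%")
})
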