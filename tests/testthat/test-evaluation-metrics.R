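test_that("confusion counts match a brute-force pairwise oracle", {
  cc <- confusion(rep(c(1L, 2L), c(6, 4)), rep(c(1L, 2L), c(6, 4)))
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 6L, FP = 0L, TN = 4L, FN = 0L))
  flipped <- confusion(c(2L, 2L, 1L), c(1L, 1L, 2L))
  expect_equal(flipped$TP + flipped$TN, 0L)
  set.seed(31)
  for (i in 1:20) {
    pred <- sample(1:2, 50, TRUE); truth <- sample(1:2, 50, TRUE)
    cc <- confusion(pred, truth)
    brute <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (j in seq_along(pred)) {
      key <- if (pred[j] == 1 && truth[j] == 1) "TP"
             else if (pred[j] == 1) "FP"
             else if (truth[j] == 2) "TN" else "FN"
      brute[key] <- brute[key] + 1L
    }
    expect_equal(unlist(cc[names(brute)]), brute)
  }
  expect_error(confusion(1L, c(1L, 2L)), "length")
})

test_that("scalar metrics follow the printed formulas with flagged zero denominators", {
  cc <- structure(list(TP = 8L, FP = 2L, TN = 8L, FN = 2L),
                  class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.8)
  none <- structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 3L),
                    class = "confusion_counts")
  m0 <- metrics(none)
  expect_equal(m0$precision, 0)
  expect_true("precision" %in% m0$flagged)
})

test_that("identities hold on random confusion counts: accuracy + BER = 1 and the two F1 forms agree", {
  set.seed(13)
  for (i in 1:1000) {
    cc <- structure(as.list(stats::setNames(sample(0:30, 4, TRUE),
                                            c("TP", "FP", "TN", "FN"))),
                    class = "confusion_counts")
    if (cc$TP + cc$FP + cc$TN + cc$FN == 0) next
    m <- metrics(cc)
    expect_equal(m$accuracy + m$ber, 1)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("ROC/AUC behaves on separable, random and tied scores", {
  truth <- rep(c(1L, 2L), c(5, 5))
  expect_equal(roc_and_auc(c(rep(1, 5), rep(0, 5)), truth)$auc, 1)
  set.seed(17)
  r <- roc_and_auc(stats::runif(1e4), sample(1:2, 1e4, TRUE))
  expect_lt(abs(r$auc - 0.5), 0.02)
})

test_that("AUC equals the Mann-Whitney statistic and is invariant to monotone transforms", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(1:2, n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(stats::rnorm(n), 1)          # ties on purpose
    auc <- roc_and_auc(scores, truth)$auc
    w <- stats::wilcox.test(scores[truth == 1], scores[truth == 2],
                            exact = FALSE)$statistic
    expect_equal(auc, unname(w) / (sum(truth == 1) * sum(truth == 2)))
    expect_equal(roc_and_auc(exp(3 * scores), truth)$auc, auc)
  }
  expect_error(roc_and_auc(1:4, rep(1L, 4)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- stats::rnorm(300)
  truth <- ifelse(scores + stats::rnorm(300) > 0, 1L, 2L)
  ours <- roc_and_auc(scores, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(truth, levels = c(2, 1)), predictor = scores)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("threshold sweep is monotone with saturated endpoints", {
  set.seed(29)
  for (i in 1:20) {
    n <- 80
    truth <- sample(1:2, n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, 0.05), n, TRUE)
    tab <- threshold_sweep(scores, truth)
    expect_true(all(diff(tab$sensitivity) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
    expect_equal(tab$sensitivity[1], 1)          # lowest threshold: all positive
  }
  tab <- threshold_sweep(c(0.1, 0.5, 0.9), c(1L, 2L, 1L))
  expect_equal(tab$specificity[nrow(tab)], 1)
})

test_that("metrics_report is internally consistent", {
  set.seed(37)
  scores <- cbind(stats::runif(50), 0)
  scores[, 2] <- 1 - scores[, 1]
  truth <- ifelse(scores[, 1] + stats::rnorm(50, sd = 0.2) > 0.5, 1L, 2L)
  rep <- metrics_report(scores, truth)
  expect_equal(rep$accuracy + rep$ber, 1)
  expect_true(all(c(rep$precision, rep$recall, rep$f1, rep$auc) >= 0))
  expect_true(all(c(rep$precision, rep$recall, rep$f1, rep$auc) <= 1))
})
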