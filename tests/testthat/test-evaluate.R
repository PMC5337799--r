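test_that("confusion counts match exhaustive enumeration", {
  # perfect prediction
  cm <- confusion(c(1, 2, 1, 2), c(1, 2, 1, 2))
  expect_identical(unname(cm[c("FP", "FN")]), c(0L, 0L))
  # all 16 truth/pred patterns of length 2 vs direct counting
  pats <- expand.grid(t1 = 1:2, t2 = 1:2, p1 = 1:2, p2 = 1:2)
  for (i in seq_len(nrow(pats))) {
    tr <- c(pats$t1[i], pats$t2[i]); pr <- c(pats$p1[i], pats$p2[i])
    cm <- confusion(tr, pr)
    expect_identical(unname(cm["TP"]), sum(tr == 2 & pr == 2))
    expect_identical(unname(cm["FP"]), sum(tr == 1 & pr == 2))
    expect_identical(unname(cm["TN"]), sum(tr == 1 & pr == 1))
    expect_identical(unname(cm["FN"]), sum(tr == 2 & pr == 1))
  }
  expect_error(confusion(c(1, 2), c(1, 2, 1)), "lengths")
  expect_error(confusion(c(1, 3), c(1, 2)), "labels")
})

test_that("the published worked example reproduces: 8 + 4 misjudged of 50 + 50", {
  truth <- rep(c(2, 1), each = 50)
  pred <- c(rep(1, 8), rep(2, 42),    # 8 labour misjudged as pregnancy
            rep(2, 4), rep(1, 46))    # 4 pregnancy misjudged as labour
  cm <- confusion(truth, pred)
  expect_identical(unname(cm[c("TP", "FN", "TN", "FP")]),
                   c(42L, 8L, 46L, 4L))
  m <- classification_metrics(cm)
  expect_equal(unname(m["accuracy"]), 88.00)
})

test_that("metrics match hand arithmetic and flag empty denominators", {
  m <- classification_metrics(c(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(unname(m), c(75.00, 50.00, 62.50))
  m2 <- classification_metrics(c(TP = 5, FN = 0, TN = 7, FP = 0))
  expect_true(all(m2 == 100))
  expect_error(classification_metrics(c(TP = 0, FN = 0, TN = 2, FP = 1)),
               "sensitivity")
  expect_error(classification_metrics(c(TP = 1, FN = 1, TN = 0, FP = 0)),
               "specificity")
  # accuracy identity: acc = (sens*P + spec*N)/(P+N)
  set.seed(19)
  for (i in 1:20) {
    cm <- c(TP = sample(1:9, 1), FP = sample(1:9, 1),
            TN = sample(1:9, 1), FN = sample(1:9, 1))
    m <- classification_metrics(cm)
    P <- cm["TP"] + cm["FN"]; N <- cm["TN"] + cm["FP"]
    expect_equal(unname(m["accuracy"]),
                 unname((m["sensitivity"] * P + m["specificity"] * N) / (P + N)))
  }
})

test_that("ROC endpoints, monotonicity and degenerate cases behave", {
  truth <- rep(c(1, 2), each = 5)
  r <- roc_curve(truth, c(1:5, 6:10))     # perfect separation
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # all-tied scores: chance
  expect_equal(roc_curve(truth, rep(1, 10))$auc, 0.5)
  expect_error(roc_curve(rep(1, 4), 1:4), "both classes")
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    truth <- c(rep(1, 3), rep(2, 3), sample(1:2, n - 6, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_curve(truth, scores)$auc, mw_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- sample(rep(1:2, each = 15))
  scores <- round(rnorm(30), 1)            # some ties
  a_pkg <- roc_curve(truth, scores)$auc
  a_ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c(1, 2),
                                          direction = "<", quiet = TRUE)))
  expect_equal(a_pkg, a_ref, tolerance = 1e-12)
})

test_that("AUC is rank-invariant and sign-antisymmetric", {
  set.seed(22)
  truth <- sample(rep(1:2, each = 10))
  scores <- rnorm(20)
  a <- roc_curve(truth, scores)$auc
  expect_equal(roc_curve(truth, exp(3 * scores))$auc, a)
  expect_equal(roc_curve(truth, -scores)$auc, 1 - a)
})
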