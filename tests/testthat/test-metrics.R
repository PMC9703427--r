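test_that("confusion counts follow the f(i,j) definition", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unclass(cc), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  cc2 <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(cc2[["fp"]] + cc2[["fn"]], 0L)
  cc3 <- confusion_counts(rep(0, 5), rep(1, 5))
  expect_identical(unclass(cc3), c(tp = 0L, fp = 5L, fn = 0L, tn = 0L))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 0)), "same length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("sensitivity/specificity/precision/F1 formulas and NA policy", {
  m <- basic_metrics(c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unname(m), c(0.5, 0.5, 0.5, 0.5))
  m2 <- basic_metrics(c(tp = 3, fp = 0, fn = 1, tn = 6))
  expect_equal(m2[["sensitivity"]], 0.75)
  expect_equal(m2[["specificity"]], 1)
  expect_equal(m2[["precision"]], 1)
  expect_equal(m2[["f1"]], 2 * 1 * 0.75 / 1.75)
  # zero denominators are values (NA), not errors
  m3 <- basic_metrics(c(tp = 0, fp = 2, fn = 0, tn = 3))
  expect_true(is.na(m3[["sensitivity"]]))
  expect_true(is.na(m3[["f1"]]))
  expect_equal(m3[["precision"]], 0)
})

test_that("confusion counts conserve length and F1 matches its count identity", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    truth <- rbinom(n, 1, 0.4)
    pred <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(truth, pred)
    expect_identical(sum(cc), n)
    m <- basic_metrics(cc)
    if (!is.na(m[["f1"]])) {
      expect_equal(m[["f1"]],
                   2 * cc[["tp"]] / (2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]))
    }
  }
})

test_that("AUC equals known values on hand cases", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 3 concordant pairs of 4
  expect_equal(roc_auc(c(0.8, 0.7, 0.6, 0.5), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "single class")
  expect_error(roc_auc(c(0.2), c(1, 0)), "same length")
})

test_that("AUC agrees with the brute-force pairwise oracle and complements", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(scores, truth), auc_bruteforce(scores, truth),
                 tolerance = 1e-12)
    if (!any(duplicated(scores))) {
      expect_equal(roc_auc(1 - scores, truth), 1 - roc_auc(scores, truth),
                   tolerance = 1e-12)
    }
  }
})
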