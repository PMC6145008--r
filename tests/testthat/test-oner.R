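test_that("discretization places one boundary between clean class runs", {
  rule <- discretize_attribute(c(3, 3.5, 4, 5, 5.5, 6),
                               c("U", "U", "U", "M", "M", "M"), min_bucket = 3)
  expect_equal(rule$boundaries, 4.5)
  expect_equal(rule$bin_labels, c("U", "M"))
  expect_equal(rule$error, 0)
  oracle <- best_split_oracle(c(3, 3.5, 4, 5, 5.5, 6), c("U", "U", "U", "M", "M", "M"))
  expect_equal(rule$boundaries, oracle$boundary)
  expect_equal(rule$error, oracle$error)
})

test_that("degenerate discretizations collapse to a single bin", {
  same <- discretize_attribute(rnorm(8), rep("M", 8), min_bucket = 3)
  expect_length(same$boundaries, 0)
  expect_equal(same$error, 0)
  inter <- discretize_attribute(1:10, rep(c("U", "M"), 5), min_bucket = 10)
  expect_length(inter$boundaries, 0)
  expect_equal(inter$error, 5)
  expect_error(discretize_attribute(1:3, c("U", "M", "U"), min_bucket = 6),
               class = "hrvci_error_bad_argument")
})

test_that("a pure class run stays in one bin even past the bucket size", {
  # 14 low-valued U then 16 high-valued M: the boundary must fall in the gap
  set.seed(8)
  v <- c(sort(runif(14, 1, 4)), sort(runif(16, 5, 8)))
  l <- c(rep("U", 14), rep("M", 16))
  rule <- discretize_attribute(v, l, min_bucket = 6)
  expect_length(rule$boundaries, 1)
  expect_gt(rule$boundaries, 4)
  expect_lt(rule$boundaries, 5)
  expect_equal(rule$error, 0)
})

test_that("fit_oner selects the cleaner separating feature", {
  set.seed(12)
  n <- 30
  diag <- c(rep("MCS", 16), rep("UWS", 14))
  sep <- ifelse(diag == "MCS", 6, 3) + runif(n, -0.5, 0.5)
  noise <- rnorm(n, 4, 1)
  d1 <- tibble::tibble(diagnosis = diag, ci_s = noise, ci_l = sep)
  m1 <- fit_oner(d1)
  expect_equal(m1$attribute, "ci_l")
  expect_equal(m1$training_error, 0)
  d2 <- tibble::tibble(diagnosis = diag, ci_s = sep, ci_l = noise)
  m2 <- fit_oner(d2)
  expect_equal(m2$attribute, "ci_s")
  # identical columns: tie broken by feature order
  d3 <- tibble::tibble(diagnosis = diag, ci_s = sep, ci_l = sep)
  expect_equal(fit_oner(d3)$attribute, "ci_s")
})

test_that("fit_oner tidiers expose the rule", {
  d <- planted_cohort(seed = 3)
  m <- fit_oner(d)
  td <- tidy(m)
  expect_equal(nrow(td), length(m$bin_labels))
  expect_equal(td$label, m$bin_labels)
  g <- glance(m)
  expect_equal(g$attribute, m$attribute)
})

test_that("zero-r predicts the majority with ties toward MCS", {
  d <- tibble::tibble(diagnosis = c(rep("MCS", 16), rep("UWS", 14)))
  expect_equal(fit_zeror(d)$prediction, "MCS")
  d2 <- tibble::tibble(diagnosis = c(rep("MCS", 14), rep("UWS", 16)))
  expect_equal(fit_zeror(d2)$prediction, "UWS")
  d3 <- tibble::tibble(diagnosis = c(rep("MCS", 15), rep("UWS", 15)))
  expect_equal(fit_zeror(d3)$prediction, "MCS")
  expect_error(fit_zeror(d3[0, , drop = FALSE]), class = "hrvci_error_bad_argument")
})

test_that("prediction assigns boundary values to the upper bin", {
  model <- structure(list(attribute = "ci_l", boundaries = 4.876,
                          bin_labels = c("UWS", "MCS"), degenerate = FALSE),
                     class = "oner_model")
  nd <- tibble::tibble(ci_l = c(5.0, 4.876, 1.0))
  expect_equal(predict(model, nd), c("MCS", "MCS", "UWS"))
  expect_error(predict(model, tibble::tibble(ci_s = 1)),
               class = "hrvci_error_bad_argument")
  expect_error(predict(model, tibble::tibble(ci_l = NA_real_)),
               class = "hrvci_error_bad_argument")
})

test_that("one-r training error never exceeds the zero-r baseline", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(12:60, 1)
    d <- tibble::tibble(
      diagnosis = sample(c("MCS", "UWS"), n, replace = TRUE, prob = c(0.6, 0.4)),
      ci_s = rnorm(n), ci_l = rnorm(n)
    )
    if (length(unique(d$diagnosis)) < 2) next
    mb <- sample(1:6, 1)
    oner <- fit_oner(d, min_bucket = min(mb, n))
    zeror <- fit_zeror(d)
    expect_lte(oner$training_error, zeror$training_error)
  }
})

test_that("the metric panel reproduces hand-computable cases", {
  perfect <- evaluate_classifier(c(rep("MCS", 16), rep("UWS", 14)),
                                 c(rep("MCS", 16), rep("UWS", 14)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  allpos <- evaluate_classifier(c(rep("MCS", 16), rep("UWS", 14)), rep("MCS", 30))
  expect_equal(allpos$accuracy, 16 / 30)
  expect_false(allpos$mcc_defined)
  expect_equal(allpos$mcc, 0)
  r <- classification_report(tp = 15, fn = 1, fp = 1, tn = 13)
  expect_equal(r$fpr, 1 - r$specificity)
  expect_equal(r$fnr, 1 - r$sensitivity)
  expect_equal(r$mcc, (15 * 13 - 1) / sqrt(16 * 16 * 14 * 14))
  expect_error(evaluate_classifier(c("MCS", "UWS"), c("MCS")),
               class = "hrvci_error_bad_argument")
  expect_error(classification_report(-1, 0, 0, 2), class = "hrvci_error_bad_argument")
})

test_that("report_table prints the conventional nine-row panel", {
  tab <- report_table(classification_report(15, 1, 1, 13))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$printed[tab$metric == "Accuracy (%)"], "93")
  expect_equal(tab$printed[tab$metric == "F1-score (%)"], "94")
  expect_equal(tab$printed[grepl("Matthews", tab$metric)], "0.87")
})

test_that("cross-validation partitions correctly and is reproducible", {
  d <- planted_cohort(seed = 10)
  cv1 <- cross_validate(d, k = 10, seed = 77)
  cv2 <- cross_validate(d, k = 10, seed = 77)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(glance(cv1), glance(cv2))
  # every record tested exactly once, fold sizes within 1
  expect_equal(nrow(cv1$predictions), nrow(d))
  sizes <- table(cv1$predictions$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # stratification keeps both classes in the larger folds
  expect_equal(cv1$pooled$tp + cv1$pooled$fn, sum(d$diagnosis == "MCS"))
  expect_equal(cv1$pooled$tn + cv1$pooled$fp, sum(d$diagnosis == "UWS"))
})

test_that("a separable cohort cross-validates to 100% accuracy", {
  d <- planted_cohort(n_mcs = 16, n_uws = 14, margin = 1, seed = 4)
  cv <- cross_validate(d, k = 10, seed = 1)
  expect_equal(cv$pooled$accuracy, 1)
})

test_that("label-permuted cohorts cross-validate near the majority prevalence", {
  set.seed(300)
  n <- 300
  d <- tibble::tibble(
    diagnosis = sample(c(rep("MCS", 160), rep("UWS", 140))),
    ci_s = rnorm(n), ci_l = rnorm(n)
  )
  cv <- cross_validate(d, k = 10, seed = 8)
  prev <- 160 / 300
  se3 <- 3 * sqrt(prev * (1 - prev) / n)
  expect_lt(abs(cv$pooled$accuracy - prev), se3 + 0.05)
})

test_that("cross-validation rejects impossible configurations", {
  d <- planted_cohort(seed = 1)
  expect_error(cross_validate(d, k = 1, seed = 1), class = "hrvci_error_bad_argument")
  expect_error(cross_validate(d, k = 31, seed = 1), class = "hrvci_error_bad_argument")
  expect_error(cross_validate(d, k = 10), class = "hrvci_error_bad_argument")
})
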