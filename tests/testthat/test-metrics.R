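test_that("confusion tables honour the target orientation", {
  ind <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  out <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  ct <- build_confusion(ind, out, "presence")
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  # absence inverts the outcome, swapping columns of the table
  ct_a <- build_confusion(ind, out, "absence")
  expect_equal(ct_a[["tp"]], ct[["fp"]])
  expect_equal(ct_a[["fn"]], ct[["tn"]])
  # all-false indicator has an empty positive row
  ct0 <- build_confusion(rep(FALSE, 5), out)
  expect_equal(ct0[["tp"]] + ct0[["fp"]], 0L)
  expect_error(build_confusion(ind, out[-1]), "length")
  expect_error(build_confusion(logical(0), logical(0)), "empty")
})

test_that("point metrics reproduce hand-checked tables", {
  # high-risk stratum of the count-based criterion on the reference cohort
  m <- compute_metrics(confusion_table(56, 13, 4, 17))
  expect_equal(m$sensitivity, 56 / 60)
  expect_equal(m$specificity, 17 / 30)
  expect_equal(m$ppv, 56 / 69)
  expect_equal(m$npv, 17 / 21)
  expect_equal(m$accuracy, 73 / 90)
  m <- compute_metrics(confusion_table(58, 9, 2, 21))
  expect_equal(round(c(m$sensitivity, m$specificity, m$ppv, m$npv,
                       m$accuracy), 3),
               c(0.967, 0.700, 0.866, 0.913, 0.878))
  # perfect classifier
  m <- compute_metrics(confusion_table(7, 0, 0, 5))
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy")], use.names = FALSE), rep(1, 5))
  expect_length(m$undefined, 0)
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  m <- compute_metrics(confusion_table(0, 0, 3, 7))
  expect_true(is.na(m$ppv))
  expect_setequal(m$undefined, "ppv")
  m <- compute_metrics(confusion_table(0, 0, 0, 7))
  expect_setequal(m$undefined, c("sensitivity", "ppv"))
  expect_equal(m$accuracy, 1)
})

test_that("binary AUC equals the mean of sensitivity and specificity", {
  expect_equal(binary_auc(confusion_table(56, 13, 4, 17)), 0.75)
  expect_equal(round(binary_auc(confusion_table(58, 10, 2, 20)), 3), 0.817)
  # property over random tables, vs an independent trapezoid computation
  for (ct in random_tables(200, seed = 11)) {
    sens <- ct[["tp"]] / (ct[["tp"]] + ct[["fn"]])
    spec <- ct[["tn"]] / (ct[["tn"]] + ct[["fp"]])
    x <- c(0, 1 - spec, 1); y <- c(0, sens, 1)
    trapezoid <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    expect_equal(binary_auc(ct), trapezoid)
  }
  # ROC endpoints
  expect_equal(binary_auc(confusion_table(9, 0, 0, 4)), 1)
  expect_equal(binary_auc(confusion_table(8, 8, 2, 2)), 0.5)
  expect_error(binary_auc(confusion_table(0, 3, 0, 7)), "positives")
})

test_that("binary AUC agrees with a rank-based ROC package on 0/1 scores", {
  for (ct in random_tables(25, seed = 13)) {
    truth <- c(rep(1, ct[["tp"]]), rep(0, ct[["fp"]]),
               rep(1, ct[["fn"]]), rep(0, ct[["tn"]]))
    score <- c(rep(1, ct[["tp"]] + ct[["fp"]]),
               rep(0, ct[["fn"]] + ct[["tn"]]))
    ref <- suppressMessages(as.numeric(pROC::auc(truth, score,
                                                 direction = "<")))
    expect_equal(binary_auc(ct), ref, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil interval matches its hand-evaluated formula", {
  ci <- auc_ci(0.75, 60, 30, 0.95)
  expect_equal(unname(ci), c(0.6495248, 0.8504752), tolerance = 1e-6)
  # symmetric about 0.5 with equal class sizes
  ci <- auc_ci(0.5, 40, 40, 0.95)
  expect_equal(unname(sum(ci)), 1, tolerance = 1e-12)
  # width shrinks monotonically with n
  widths <- vapply(c(10, 40, 160, 640),
                   function(n) diff(auc_ci(0.8, n, n, 0.95)), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(auc_ci(1.0, 60, 30), "between 0 and 1")
  expect_error(auc_ci(0.7, 1, 30), "at least 2")
  expect_error(auc_ci(0.7, 60, 30, level = 1.2), "level")
})

test_that("chi-square matches brute-force expected counts and a stats oracle", {
  cs <- chi_square_p(confusion_table(2, 0, 28, 60))
  expect_equal(cs$statistic, 4.0909091, tolerance = 1e-6)
  expect_equal(cs$p_value, 0.0431, tolerance = 1e-3)
  for (ct in random_tables(1000, seed = 17)) {
    cs <- chi_square_p(ct)
    expect_equal(cs$statistic, pearson_brute_force(ct), tolerance = 1e-10)
  }
  # cross-check against stats::chisq.test without continuity correction
  ct <- confusion_table(56, 13, 4, 17)
  ref <- suppressWarnings(stats::chisq.test(
    matrix(c(56, 4, 13, 17), nrow = 2), correct = FALSE))
  cs <- chi_square_p(ct)
  expect_equal(cs$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cs$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(cs$p_value, 1e-4)
  # independence (proportional rows) gives a null statistic
  expect_equal(chi_square_p(confusion_table(10, 5, 20, 10))$statistic, 0)
  expect_equal(chi_square_p(confusion_table(10, 5, 20, 10))$p_value, 1)
  # zero margin: undefined, flagged
  cs <- chi_square_p(confusion_table(0, 0, 28, 60))
  expect_true(cs$undefined)
  expect_true(is.na(cs$p_value))
})

test_that("sample size formula reproduces textbook values and scaling", {
  expect_equal(sample_size_accuracy(0.5, 0.05, 0.95), 385L)
  expect_equal(sample_size_accuracy(0.7, 0.10, 0.95), 81L)
  expect_equal(sample_size_accuracy(0.7, 0.05, 0.95), 323L)
  # halving the margin roughly quadruples n (up to ceiling)
  n1 <- sample_size_accuracy(0.6, 0.08)
  n2 <- sample_size_accuracy(0.6, 0.04)
  expect_true(abs(n2 - 4 * n1) <= 4)
  expect_error(sample_size_accuracy(1, 0.05), "between 0 and 1")
})

test_that("reading the complement stratum against the opposite target swaps sens/spec and ppv/npv, fixing accuracy and AUC", {
  # e.g. 'high risk predicts presence' and 'not-high-risk predicts absence'
  # describe the same 2x2 association from opposite corners
  set.seed(19)
  for (i in 1:50) {
    ind <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    out <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (!any(ind) || all(ind) || !any(out) || all(out)) next
    mp <- compute_metrics(build_confusion(ind, out, "presence"))
    ma <- compute_metrics(build_confusion(!ind, out, "absence"))
    expect_equal(mp$sensitivity, ma$specificity)
    expect_equal(mp$specificity, ma$sensitivity)
    expect_equal(mp$ppv, ma$npv)
    expect_equal(mp$npv, ma$ppv)
    expect_equal(mp$accuracy, ma$accuracy)
    expect_equal(binary_auc(build_confusion(ind, out, "presence")),
                 binary_auc(build_confusion(!ind, out, "absence")))
  }
})
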