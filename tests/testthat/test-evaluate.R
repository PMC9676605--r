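test_that("evaluation report covers every criterion-stratum pair with the documented policies", {
  report <- evaluate_cohort(reconstruct_cohort())
  rows <- report$rows
  expect_equal(nrow(rows), 9L)
  expect_equal(sort(unique(rows$criterion)), c("ASGE", "ESGE", "SAGES"))
  expect_equal(rows$target, rep(c("presence", "presence", "absence"), 3))
  expect_equal(rows$policy[rows$criterion == "SAGES"], rep("exclusive", 3))
  expect_equal(rows$policy[rows$criterion == "ASGE"],
               c("indicator", "indicator", "complement_of_hr"))
  expect_equal(rows$policy[rows$criterion == "ESGE"],
               c("indicator", "indicator", "strict"))
  # each row's cells sum to the cohort size
  expect_true(all(rows$tp + rows$fp + rows$fn + rows$tn == report$summary$n))
  # intermediate-risk strata are flagged when discrimination is poor
  expect_true(all(rows$suboptimal_discrimination[rows$stratum == "IR"]))
  expect_false(any(rows$suboptimal_discrimination[rows$stratum != "IR"]))
})

test_that("recomputing each row's metrics from its own cells reproduces the row", {
  rows <- evaluate_cohort(reconstruct_cohort())$rows
  for (i in seq_len(nrow(rows))) {
    ct <- confusion_table(rows$tp[i], rows$fp[i], rows$fn[i], rows$tn[i])
    m <- compute_metrics(ct)
    expect_equal(rows$sensitivity[i], m$sensitivity)
    expect_equal(rows$specificity[i], m$specificity)
    expect_equal(rows$accuracy[i], m$accuracy)
    expect_equal(rows$auc[i], binary_auc(ct))
    expect_equal(rows$p_value[i], chi_square_p(ct)$p_value)
  }
})

test_that("accuracy identity holds on every report row", {
  rows <- evaluate_cohort(simulate_cohort(simulation_params(n = 250,
                                                            seed = 21)))$rows
  n_pos <- rows$tp + rows$fn
  n_neg <- rows$tn + rows$fp
  expect_equal(rows$accuracy,
               (rows$sensitivity * n_pos + rows$specificity * n_neg) /
                 (n_pos + n_neg))
})

test_that("perfectly separated two-patient cohort scores 1 everywhere in HR", {
  cohort <- tibble::tibble(
    patient_id = c("A", "B"),
    age = c(50, 40),
    sex = c("male", "female"),
    total_bilirubin_mgdl = c(5.0, 0.8),
    lft_abnormal = c(TRUE, FALSE),
    cbd_diameter_mm = c(10, 4),
    stone_on_imaging = c(TRUE, FALSE),
    cholangitis = c(FALSE, FALSE),
    ercp_stone = c(TRUE, FALSE)
  )
  rows <- evaluate_cohort(cohort)$rows
  hr <- rows[rows$stratum == "HR", ]
  expect_equal(hr$sensitivity, rep(1, 3))
  expect_equal(hr$specificity, rep(1, 3))
  expect_equal(hr$accuracy, rep(1, 3))
})

test_that("single-class cohorts are rejected", {
  cohort <- reconstruct_cohort()
  cohort$ercp_stone <- TRUE
  expect_error(evaluate_cohort(cohort), "single outcome class")
})

test_that("rendered reports are deterministic and lossless", {
  report <- evaluate_cohort(reconstruct_cohort())
  j1 <- render_report(report, "json")
  j2 <- render_report(evaluate_cohort(reconstruct_cohort()), "json")
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$rows$accuracy, report$rows$accuracy)
  expect_equal(parsed$rows$tp, report$rows$tp)
  expect_equal(parsed$summary$n, 90)
  csv <- render_report(report, "csv")
  expect_equal(length(csv), nrow(report$rows) + 1L)
  expect_error(render_report(report, "xml"), "arg")
})

test_that("text rendering prints the headline row with display rounding", {
  txt <- render_report(evaluate_cohort(reconstruct_cohort()), "text")
  sages_hr <- grep("^SAGES", txt, value = TRUE)[1]
  expect_match(sages_hr, "93.3")
  expect_match(sages_hr, "56.7")  # 17/30 rounded to one decimal
  expect_match(sages_hr, "81.1")
  expect_match(sages_hr, "<0.0001")
  expect_match(paste(txt, collapse = "\n"), "0.750")
})

test_that("ROC points mirror the report rows", {
  report <- evaluate_cohort(reconstruct_cohort())
  pts <- roc_points(report)
  expect_equal(nrow(pts), nrow(report$rows))
  expect_equal(pts$tpr, report$rows$sensitivity)
  expect_equal(pts$fpr, 1 - report$rows$specificity)
})

test_that("end-to-end: same CSV in, byte-identical JSON report out", {
  path <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(simulation_params(n = 80, seed = 55)), path)
  j1 <- render_report(evaluate_cohort(read_cohort(path)), "json")
  j2 <- render_report(evaluate_cohort(read_cohort(path)), "json")
  expect_identical(j1, j2)
})
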