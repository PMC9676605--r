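# Shared oracles and generators, independent of the implementation paths
# they check.

# Random non-degenerate 2x2 tables (all margins positive).
random_tables <- function(n_tables, seed, max_cell = 60L) {
  set.seed(seed)
  out <- vector("list", n_tables)
  i <- 1L
  while (i <= n_tables) {
    cells <- sample.int(max_cell, 4L, replace = TRUE)
    ct <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    margins <- c(ct[["tp"]] + ct[["fp"]], ct[["fn"]] + ct[["tn"]],
                 ct[["tp"]] + ct[["fn"]], ct[["fp"]] + ct[["tn"]])
    if (all(margins > 0)) {
      out[[i]] <- ct
      i <- i + 1L
    }
  }
  out
}

# Brute-force Pearson chi-square via expected-count summation over the
# four cells, the textbook definition.
pearson_brute_force <- function(ct) {
  obs <- matrix(c(ct[["tp"]], ct[["fn"]], ct[["fp"]], ct[["tn"]]), nrow = 2)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expected)^2 / expected)
}

# A tiny hand-built cohort exercising every factor combination relevant to
# the three criteria.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = paste0("T", 1:6),
    age = c(45, 60, 30, 70, 50, 40),
    sex = rep(c("male", "female"), 3),
    total_bilirubin_mgdl = c(2.0, 4.5, 0.9, 1.0, 5.0, 1.2),
    lft_abnormal = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    cbd_diameter_mm = c(8, 9, 6, 5, 10, 4),
    stone_on_imaging = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    cholangitis = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    ercp_stone = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
}

# All 2^4 SAGES factor combinations as a factor table (other flags set
# consistently with the implication invariants).
all_sages_combos <- function() {
  g <- expand.grid(imaging_stone = c(FALSE, TRUE), dilated_cbd = c(FALSE, TRUE),
                   cholangitis = c(FALSE, TRUE), tb_over_sages = c(FALSE, TRUE))
  tibble::tibble(
    patient_id = sprintf("C%02d", seq_len(nrow(g))),
    imaging_stone = g$imaging_stone,
    dilated_cbd = g$dilated_cbd,
    cholangitis = g$cholangitis,
    tb_over_sages = g$tb_over_sages,
    tb_over_asge = FALSE,
    lft_abnormal = g$tb_over_sages,
    age_over_asge = FALSE
  )
}
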