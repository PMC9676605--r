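criteria_names <- function() c("SAGES", "ASGE", "ESGE")

# The stratum indicator each report row uses, per criterion. HR rows
# predict stone presence; IR rows (indicator membership for ASGE/ESGE,
# exclusive for SAGES) predict presence; LR rows predict absence, with the
# criterion-specific low-risk reading: exclusive zero-factor stratum for
# SAGES, complement of meets-HR for ASGE, strict no-factor membership for
# ESGE.
row_indicator <- function(assignment, criterion, stratum) {
  switch(paste(criterion, stratum),
    "SAGES HR" = assignment$exclusive_stratum == "HR",
    "SAGES IR" = assignment$exclusive_stratum == "IR",
    "SAGES LR" = assignment$exclusive_stratum == "LR",
    "ASGE HR" = assignment$meets_hr,
    "ASGE IR" = assignment$meets_ir,
    "ASGE LR" = !assignment$meets_hr,
    "ESGE HR" = assignment$meets_hr,
    "ESGE IR" = assignment$meets_ir,
    "ESGE LR" = assignment$meets_strict_lr,
    stop("unknown criterion/stratum", call. = FALSE)
  )
}

row_policy <- function(criterion, stratum) {
  switch(paste(criterion, stratum),
    "SAGES HR" = , "SAGES IR" = , "SAGES LR" = "exclusive",
    "ASGE HR" = , "ESGE HR" = "indicator",
    "ASGE IR" = , "ESGE IR" = "indicator",
    "ASGE LR" = "complement_of_hr",
    "ESGE LR" = "strict"
  )
}

#' Evaluate all three risk criteria against the ERCP gold standard
#'
#' Runs the full pipeline — factor derivation, stratification under all
#' three criteria, confusion tables and every accuracy statistic — and
#' returns one report row per criterion and stratum. High- and
#' intermediate-risk rows score the stratum as a predictor of stone
#' *presence*; low-risk rows score it as a predictor of stone *absence*
#' (outcome inverted). Intermediate-risk rows are flagged
#' `suboptimal_discrimination` when their AUC falls below 0.6; they are
#' reported regardless so the AUC tables are complete.
#'
#' @param cohort A patient cohort with at least one stone-positive and one
#'   stone-negative record.
#' @param thresholds A `cbd_thresholds` object.
#' @param conf_level Confidence level for the Hanley-McNeil AUC interval.
#' @return A `cbd_evaluation` object: list with `rows` (tibble: criterion,
#'   stratum, policy, target, tp/fp/fn/tn, all metrics, AUC with CI,
#'   chi-square p), `summary` (cohort size, stone count, factor
#'   prevalences) and `provenance` (thresholds, package version, input
#'   digest).
#' @examples
#' report <- evaluate_cohort(reconstruct_cohort())
#' report$rows[report$rows$stratum == "HR", c("criterion", "accuracy", "auc")]
#' @export
evaluate_cohort <- function(cohort, thresholds = criterion_thresholds(),
                            conf_level = 0.95) {
  cohort <- validate_cohort(cohort, thresholds)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  outcome <- cohort$ercp_stone
  if (all(outcome) || !any(outcome)) {
    stop("cohort has a single outcome class; AUC against the gold ",
         "standard is undefined", call. = FALSE)
  }
  factors <- derive_factors(cohort, thresholds)
  assignments <- list(
    SAGES = stratify_cohort(cohort, "sages", thresholds),
    ASGE  = stratify_cohort(cohort, "asge", thresholds),
    ESGE  = stratify_cohort(cohort, "esge", thresholds)
  )
  grid <- expand.grid(stratum = risk_levels(), criterion = criteria_names(),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    criterion <- grid$criterion[i]
    stratum <- grid$stratum[i]
    target <- if (stratum == "LR") "absence" else "presence"
    ind <- row_indicator(assignments[[criterion]], criterion, stratum)
    ct <- build_confusion(ind, outcome, target)
    m <- compute_metrics(ct)
    auc <- binary_auc(ct)
    ci <- auc_ci_or_na(auc, ct, conf_level)
    chi <- chi_square_p(ct)
    tibble(
      criterion = criterion, stratum = stratum,
      policy = row_policy(criterion, stratum), target = target,
      n_stratum = sum(ind),
      tp = ct[["tp"]], fp = ct[["fp"]], fn = ct[["fn"]], tn = ct[["tn"]],
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
      auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
      chi_sq = chi$statistic, p_value = chi$p_value,
      suboptimal_discrimination = stratum == "IR" && auc < 0.6
    )
  })
  rows <- dplyr::bind_rows(rows)
  structure(
    list(
      rows = rows,
      summary = list(
        n = nrow(cohort),
        n_stone = sum(outcome),
        factor_prevalence = colSums(factors[, factor_columns()])
      ),
      provenance = list(
        thresholds = unclass(thresholds),
        package_version = as.character(utils::packageVersion("cbdrisk")),
        conf_level = conf_level,
        input_digest = cohort_digest(cohort)
      )
    ),
    class = "cbd_evaluation"
  )
}

auc_ci_or_na <- function(auc, ct, conf_level) {
  n_pos <- ct[["tp"]] + ct[["fn"]]
  n_neg <- ct[["tn"]] + ct[["fp"]]
  if (auc <= 0 || auc >= 1 || n_pos < 2 || n_neg < 2) {
    return(c(NA_real_, NA_real_))
  }
  auc_ci(auc, n_pos, n_neg, conf_level)
}

# Small order-sensitive content digest (FNV-1a over the serialized CSV
# text), dependency-free; identifies the input in report provenance.
cohort_digest <- function(cohort) {
  txt <- paste(
    capture.output(write.csv(as.data.frame(cohort), row.names = FALSE)),
    collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte only (inputs are ASCII/UTF-8 bytes < 256),
    # keeping h representable exactly as a double
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply in exact double arithmetic (split at 2^16)
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("fnv1a:%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' ROC operating points of every report row
#'
#' One `(fpr, tpr)` operating point per (criterion, stratum) row, with the
#' trivial ROC endpoints implied; suitable for plotting or export.
#'
#' @param report A `cbd_evaluation` object.
#' @return A tibble with columns `criterion`, `stratum`, `target`, `fpr`,
#'   `tpr`.
#' @export
roc_points <- function(report) {
  stopifnot(inherits(report, "cbd_evaluation"))
  r <- report$rows
  tibble(criterion = r$criterion, stratum = r$stratum, target = r$target,
         fpr = 1 - r$specificity, tpr = r$sensitivity)
}

#' Serialize an evaluation report
#'
#' `"text"` prints the two accuracy tables (high-risk strata predicting
#' stone presence; low-risk strata predicting absence) and the AUC table
#' with display rounding: percentages to one decimal, AUC to three.
#' `"csv"` and `"json"` are lossless full-precision exports of the report
#' rows (JSON also carries the summary and provenance); both are
#' deterministic for a given report.
#'
#' @param report A `cbd_evaluation` object.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional file to write to; otherwise the serialized report
#'   is returned as a character vector.
#' @return Character vector of the serialized report (invisibly when
#'   `path` is given).
#' @export
render_report <- function(report, format = c("text", "csv", "json"),
                          path = NULL) {
  stopifnot(inherits(report, "cbd_evaluation"))
  format <- match.arg(format)
  out <- switch(format,
    text = render_text(report),
    csv = capture.output(
      write.csv(as.data.frame(report$rows), row.names = FALSE)),
    json = jsonlite::toJSON(
      list(rows = report$rows, summary = report$summary,
           provenance = report$provenance),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  )
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

render_text <- function(report) {
  r <- report$rows
  pct <- function(v) ifelse(is.na(v), "  --", sprintf("%.1f", 100 * v))
  fmt_p <- function(p) ifelse(is.na(p), "--",
                              ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
  line_for <- function(row) {
    sprintf("%-6s %6s %6s %6s %6s %6s   (%d/%d/%d/%d)  p=%s",
            row$criterion, pct(row$sensitivity), pct(row$specificity),
            pct(row$ppv), pct(row$npv), pct(row$accuracy),
            row$tp, row$fp, row$fn, row$tn, fmt_p(row$p_value))
  }
  block <- function(stratum, title) {
    sub <- r[r$stratum == stratum, ]
    c(title,
      sprintf("%-6s %6s %6s %6s %6s %6s   %s  %s", "score", "sens", "spec",
              "PPV", "NPV", "acc", "(tp/fp/fn/tn)", "P value"),
      vapply(seq_len(nrow(sub)), function(i) line_for(sub[i, ]),
             character(1)))
  }
  auc_block <- c(
    "AUC (binary-indicator, three-point ROC):",
    vapply(seq_len(nrow(r)), function(i) {
      sprintf("  %-6s %-2s (%s) %5.3f%s", r$criterion[i], r$stratum[i],
              r$target[i], r$auc[i],
              if (isTRUE(r$suboptimal_discrimination[i])) "  [suboptimal]" else "")
    }, character(1)))
  c(sprintf("Cohort: n = %d, ERCP-confirmed stones = %d",
            report$summary$n, report$summary$n_stone),
    "",
    block("HR", "High-risk strata predicting stone PRESENCE (%):"),
    "",
    block("IR", "Intermediate-risk strata predicting stone PRESENCE (%):"),
    "",
    block("LR", "Low-risk strata predicting stone ABSENCE (%):"),
    "",
    auc_block)
}

#' @export
print.cbd_evaluation <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
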