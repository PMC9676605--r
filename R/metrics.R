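#' Build a 2x2 confusion table of a binary indicator against ERCP outcome
#'
#' Cross-tabulates a stratum indicator against the gold-standard stone
#' outcome. With `target = "presence"` a true positive is indicator TRUE
#' and stone present; with `target = "absence"` the outcome is inverted,
#' so a true positive is indicator TRUE and stone absent — the orientation
#' used when a low-risk stratum is read as a prediction that no stone will
#' be found.
#'
#' @param indicator Logical vector: stratum membership per patient.
#' @param outcome Logical vector: ERCP-confirmed stone per patient.
#' @param target `"presence"` (default) or `"absence"`.
#' @return A `cbd_confusion` object: named integer counts `tp`, `fp`,
#'   `fn`, `tn` with the target stored as an attribute.
#' @examples
#' a <- stratify_cohort(reconstruct_cohort(), "sages")
#' build_confusion(a$meets_hr, reconstruct_cohort()$ercp_stone)
#' @export
build_confusion <- function(indicator, outcome,
                            target = c("presence", "absence")) {
  target <- match.arg(target)
  if (!is.logical(indicator) || !is.logical(outcome)) {
    stop("indicator and outcome must be logical vectors", call. = FALSE)
  }
  if (length(indicator) != length(outcome)) {
    stop("indicator (", length(indicator), ") and outcome (",
         length(outcome), ") differ in length", call. = FALSE)
  }
  if (length(indicator) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(indicator) || anyNA(outcome)) {
    stop("missing values in indicator or outcome", call. = FALSE)
  }
  truth <- if (target == "presence") outcome else !outcome
  structure(
    c(tp = sum(indicator & truth),
      fp = sum(indicator & !truth),
      fn = sum(!indicator & truth),
      tn = sum(!indicator & !truth)),
    target = target,
    class = "cbd_confusion"
  )
}

#' Construct a confusion table from raw cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param target Orientation label carried for reporting.
#' @return A `cbd_confusion` object.
#' @export
confusion_table <- function(tp, fp, fn, tn, target = "presence") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("confusion table is empty", call. = FALSE)
  structure(as.integer(cells), names = names(cells),
            target = target, class = "cbd_confusion")
}

#' @export
print.cbd_confusion <- function(x, ...) {
  cat(sprintf("2x2 confusion (target: %s of stone), n = %d\n",
              attr(x, "target"), sum(x)))
  print(matrix(x[c("tp", "fn", "fp", "tn")], nrow = 2,
               dimnames = list(indicator = c("positive", "negative"),
                               truth = c("positive", "negative"))))
  invisible(x)
}

#' Point diagnostic accuracy statistics of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, and overall
#' accuracy `(tp+tn)/n`. A metric whose denominator is zero is undefined
#' for that table: it is returned as `NA` and listed in the `undefined`
#' element, never silently coerced to 0 or NaN.
#'
#' @param ct A `cbd_confusion` object.
#' @return A `cbd_metrics` object: list with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (fractions in `[0, 1]` or
#'   `NA`) and `undefined` (character vector of metric names with a zero
#'   denominator).
#' @examples
#' compute_metrics(confusion_table(56, 13, 4, 17))
#' @export
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "cbd_confusion"))
  tp <- ct[["tp"]]; fp <- ct[["fp"]]; fn <- ct[["fn"]]; tn <- ct[["tn"]]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn),
    accuracy    = (tp + tn) / sum(ct)
  )
  m$undefined <- names(m)[vapply(m, is.na, logical(1))]
  structure(m, class = "cbd_metrics")
}

#' @export
print.cbd_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(
    "sensitivity %s | specificity %s | PPV %s | NPV %s | accuracy %s\n",
    pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
    pct(x$accuracy)))
  invisible(x)
}

#' Area under the ROC curve of a binary indicator
#'
#' A yes/no predictor has a single operating point, so its ROC curve is the
#' three-point polyline (0,0) - (1-specificity, sensitivity) - (1,1) and
#' the trapezoidal area reduces to `(sensitivity + specificity) / 2`. This
#' is the AUC reported for a risk stratum used as a binary test; no
#' rank-based AUC over a continuous score is involved.
#'
#' @param ct A `cbd_confusion` object with at least one positive and one
#'   negative according to the table's target orientation.
#' @return The AUC as a fraction in `[0, 1]`.
#' @examples
#' binary_auc(confusion_table(56, 13, 4, 17))  # 0.75
#' @export
binary_auc <- function(ct) {
  stopifnot(inherits(ct, "cbd_confusion"))
  n_pos <- ct[["tp"]] + ct[["fn"]]
  n_neg <- ct[["tn"]] + ct[["fp"]]
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined: the table has no ",
         if (n_pos == 0L) "positives" else "negatives", call. = FALSE)
  }
  sens <- ct[["tp"]] / n_pos
  spec <- ct[["tn"]] / n_neg
  (sens + spec) / 2
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard error
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`:
#' `SE^2 = (A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)) /
#' (n_pos * n_neg)`. The interval is clipped to `[0, 1]`.
#'
#' @param auc AUC point estimate, strictly between 0 and 1.
#' @param n_pos,n_neg Numbers of gold-standard positives and negatives
#'   (each at least 2).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' auc_ci(0.75, 60, 30)
#' @export
auc_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  if (!is.numeric(auc) || length(auc) != 1L || auc <= 0 || auc >= 1) {
    stop("auc must be strictly between 0 and 1", call. = FALSE)
  }
  if (n_pos < 2 || n_neg < 2) {
    stop("need at least 2 positives and 2 negatives", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Pearson chi-square test of association for a 2x2 table
#'
#' Classic Pearson statistic without continuity correction,
#' `X^2 = n (tp*tn - fp*fn)^2 / ((tp+fp)(fn+tn)(tp+fn)(fp+tn))`, referred
#' to the upper tail of the chi-square distribution on one degree of
#' freedom. If any margin of the table is zero the statistic is undefined
#' and both values are returned as `NA` with `undefined = TRUE`.
#'
#' @param ct A `cbd_confusion` object.
#' @return List with `statistic`, `p_value`, `df` (1) and `undefined`.
#' @examples
#' chi_square_p(confusion_table(2, 0, 28, 60))  # p ~ 0.043
#' @export
chi_square_p <- function(ct) {
  stopifnot(inherits(ct, "cbd_confusion"))
  tp <- ct[["tp"]]; fp <- ct[["fp"]]; fn <- ct[["fn"]]; tn <- ct[["tn"]]
  n <- sum(ct)
  margins <- c(tp + fp, fn + tn, tp + fn, fp + tn)
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L,
                undefined = TRUE))
  }
  stat <- n * (tp * tn - fp * fn)^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L, undefined = FALSE)
}

#' Sample size for estimating a diagnostic accuracy proportion
#'
#' Standard normal-approximation formula for estimating a proportion `p`
#' to within an absolute margin `d` at a given confidence level:
#' `n = ceiling(z^2 p (1 - p) / d^2)` with `z` the two-sided normal
#' quantile.
#'
#' @param expected_accuracy Anticipated proportion, strictly in (0, 1).
#' @param margin Absolute margin of error, strictly in (0, 1).
#' @param confidence Confidence level, strictly in (0, 1); default 0.95.
#' @return Required sample size (integer).
#' @examples
#' sample_size_accuracy(0.5, 0.05)  # 385
#' sample_size_accuracy(0.7, 0.10)  # 81
#' @export
sample_size_accuracy <- function(expected_accuracy, margin,
                                 confidence = 0.95) {
  for (v in list(expected_accuracy, margin, confidence)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("expected_accuracy, margin and confidence must all be strictly ",
           "between 0 and 1", call. = FALSE)
    }
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * expected_accuracy * (1 - expected_accuracy) /
                       margin^2))
}
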