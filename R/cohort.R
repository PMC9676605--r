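#' @keywords internal
"_PACKAGE"

#' @importFrom tibble tibble as_tibble
#' @importFrom stats pchisq qnorm rlnorm rnorm runif
#' @importFrom utils read.csv write.csv capture.output
NULL

# Required patient-level columns, in canonical CSV order.
cohort_columns <- function() {
  c("patient_id", "age", "sex", "total_bilirubin_mgdl", "lft_abnormal",
    "cbd_diameter_mm", "stone_on_imaging", "cholangitis", "ercp_stone")
}

cohort_logical_columns <- function() {
  c("lft_abnormal", "stone_on_imaging", "cholangitis", "ercp_stone")
}

#' Validate a patient cohort table
#'
#' Checks that a cohort tibble carries every required column with the right
#' type and that each record satisfies the domain invariants: positive age,
#' non-negative bilirubin and duct diameter, sex coded `"male"`/`"female"`,
#' and no missing value in a required field. Violations are reported with
#' the offending `patient_id` (or row number) and field name.
#'
#' @param cohort A data frame of patient records (see [read_cohort()] for
#'   the column schema).
#' @param thresholds Optional `cbd_thresholds`; when supplied, records with
#'   total bilirubin above the SAGES cut-off but `lft_abnormal = FALSE` are
#'   rejected (an elevated bilirubin *is* a deranged liver function test).
#' @return The cohort as a tibble, invisibly classed for downstream use.
#' @export
validate_cohort <- function(cohort, thresholds = NULL) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0L) return(cohort)

  ids <- as.character(cohort$patient_id)
  ids[is.na(ids) | ids == ""] <- paste0("<row ", which(is.na(ids) | ids == ""), ">")
  fail <- function(field, bad, why) {
    stop("invalid cohort: field `", field, "` ", why, " for patient(s) ",
         paste(utils::head(ids[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
         call. = FALSE)
  }

  for (col in cohort_columns()) {
    bad <- is.na(cohort[[col]])
    if (any(bad)) fail(col, bad, "is missing")
  }
  for (col in cohort_logical_columns()) {
    if (!is.logical(cohort[[col]])) {
      stop("cohort column `", col, "` must be logical (TRUE/FALSE)",
           call. = FALSE)
    }
  }
  if (!is.numeric(cohort$age) || !is.numeric(cohort$total_bilirubin_mgdl) ||
      !is.numeric(cohort$cbd_diameter_mm)) {
    stop("age, total_bilirubin_mgdl and cbd_diameter_mm must be numeric",
         call. = FALSE)
  }
  bad <- cohort$age <= 0
  if (any(bad)) fail("age", bad, "must be positive")
  bad <- cohort$total_bilirubin_mgdl < 0
  if (any(bad)) fail("total_bilirubin_mgdl", bad, "must be non-negative")
  bad <- cohort$cbd_diameter_mm < 0
  if (any(bad)) fail("cbd_diameter_mm", bad, "must be non-negative")
  bad <- !(cohort$sex %in% c("male", "female"))
  if (any(bad)) fail("sex", bad, "must be 'male' or 'female'")
  if (!is.null(thresholds)) {
    stopifnot(inherits(thresholds, "cbd_thresholds"))
    bad <- cohort$total_bilirubin_mgdl > thresholds$sages_tb_mgdl &
      !cohort$lft_abnormal
    if (any(bad)) {
      fail("lft_abnormal", bad,
           "must be TRUE when total bilirubin exceeds the reference cut-off")
    }
  }
  cohort
}
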