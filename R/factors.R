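#' Derive the boolean risk factors consumed by all three criteria
#'
#' Turns raw patient fields into the seven boolean factors the SAGES, ASGE
#' 2019 and ESGE rules are written in terms of. Every threshold comparison
#' is strict: `dilated_cbd` requires a duct diameter strictly greater than
#' the cut-off, `tb_over_sages`/`tb_over_asge` a bilirubin strictly above
#' the respective cut-off, `age_over_asge` an age strictly above the age
#' cut-off.
#'
#' The derived flags satisfy, by construction:
#' `tb_over_asge` implies `tb_over_sages`, and `tb_over_sages` implies
#' `lft_abnormal` (an elevated bilirubin is itself a deranged liver
#' function test; `lft_abnormal` may additionally be set by elevated
#' ALT/AST/ALP recorded upstream).
#'
#' @param cohort A validated patient cohort (see [validate_cohort()]).
#' @param thresholds A `cbd_thresholds` object; defaults to the published
#'   cut-offs via [criterion_thresholds()].
#' @return A tibble with `patient_id` and logical columns `imaging_stone`,
#'   `dilated_cbd`, `cholangitis`, `tb_over_sages`, `tb_over_asge`,
#'   `lft_abnormal`, `age_over_asge`; one row per record, order preserved.
#' @examples
#' cohort <- reconstruct_cohort()
#' factors <- derive_factors(cohort)
#' colSums(factors[-1])
#' @export
derive_factors <- function(cohort, thresholds = criterion_thresholds()) {
  stopifnot(inherits(thresholds, "cbd_thresholds"))
  cohort <- validate_cohort(cohort, thresholds)
  tb <- cohort$total_bilirubin_mgdl
  tibble(
    patient_id    = as.character(cohort$patient_id),
    imaging_stone = cohort$stone_on_imaging,
    dilated_cbd   = cohort$cbd_diameter_mm > thresholds$cbd_dilated_mm,
    cholangitis   = cohort$cholangitis,
    tb_over_sages = tb > thresholds$sages_tb_mgdl,
    tb_over_asge  = tb > thresholds$asge_tb_mgdl,
    # direct flag wins; bilirubin above the reference range forces it TRUE
    lft_abnormal  = cohort$lft_abnormal | tb > thresholds$sages_tb_mgdl,
    age_over_asge = cohort$age > thresholds$asge_age_years
  )
}

factor_columns <- function() {
  c("imaging_stone", "dilated_cbd", "cholangitis", "tb_over_sages",
    "tb_over_asge", "lft_abnormal", "age_over_asge")
}

validate_factors <- function(factors) {
  if (!is.data.frame(factors)) stop("factors must be a data frame", call. = FALSE)
  missing_cols <- setdiff(factor_columns(), names(factors))
  if (length(missing_cols)) {
    stop("factor table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in factor_columns()) {
    if (!is.logical(factors[[col]]) || anyNA(factors[[col]])) {
      stop("factor column `", col, "` must be logical with no missing values",
           call. = FALSE)
    }
  }
  if (any(factors$tb_over_asge & !factors$tb_over_sages)) {
    stop("inconsistent factors: tb_over_asge implies tb_over_sages",
         call. = FALSE)
  }
  if (any(factors$tb_over_sages & !factors$lft_abnormal)) {
    stop("inconsistent factors: tb_over_sages implies lft_abnormal",
         call. = FALSE)
  }
  invisible(factors)
}
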