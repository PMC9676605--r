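risk_levels <- function() c("HR", "IR", "LR")

new_stratum <- function(x) factor(x, levels = risk_levels(), ordered = FALSE)

#' Stratify by the SAGES four-factor count rule
#'
#' SAGES counts four risk factors per patient — stone visible on imaging,
#' dilated common bile duct, ascending cholangitis, and total bilirubin
#' above the reference cut-off — and assigns high risk for two or more
#' factors, intermediate risk for exactly one, low risk for none. The rule
#' is inherently exclusive: the three strata partition any cohort.
#'
#' @param factors A factor table from [derive_factors()].
#' @return A factor vector (levels `HR`, `IR`, `LR`), one value per record.
#' @examples
#' f <- derive_factors(reconstruct_cohort())
#' table(sages_stratify(f))
#' @export
sages_stratify <- function(factors) {
  validate_factors(factors)
  n_factors <- factors$imaging_stone + factors$dilated_cbd +
    factors$cholangitis + factors$tb_over_sages
  new_stratum(ifelse(n_factors >= 2L, "HR", ifelse(n_factors == 1L, "IR", "LR")))
}

# Shared shape of an ASGE/ESGE assignment: indicator memberships plus the
# exclusive stratum obtained by the HR > IR > LR hierarchy.
assignment_tibble <- function(criterion, patient_id, meets_hr, meets_ir) {
  tibble(
    patient_id = patient_id,
    criterion = criterion,
    exclusive_stratum = new_stratum(
      ifelse(meets_hr, "HR", ifelse(meets_ir, "IR", "LR"))
    ),
    meets_hr = meets_hr,
    meets_ir = meets_ir,
    meets_strict_lr = !meets_hr & !meets_ir
  )
}

#' Stratify by the ASGE 2019 criterion
#'
#' High risk is a disjunction: stone on imaging, ascending cholangitis, or
#' total bilirubin above the higher cut-off together with a dilated duct.
#' The intermediate-risk factors — abnormal liver function tests, age above
#' the cut-off, or a dilated duct — are *indicator* memberships: a
#' high-risk patient usually meets them too. Both readings are returned:
#' `meets_hr`/`meets_ir` as independent indicators, and
#' `exclusive_stratum` resolving overlap by the HR > IR > LR hierarchy.
#' `meets_strict_lr` is true only when no listed factor is present.
#'
#' @inheritParams sages_stratify
#' @return A tibble with columns `patient_id`, `criterion`,
#'   `exclusive_stratum`, `meets_hr`, `meets_ir`, `meets_strict_lr`.
#' @export
asge_stratify <- function(factors) {
  validate_factors(factors)
  meets_hr <- factors$imaging_stone | factors$cholangitis |
    (factors$tb_over_asge & factors$dilated_cbd)
  meets_ir <- factors$lft_abnormal | factors$age_over_asge | factors$dilated_cbd
  assignment_tibble("ASGE", factors$patient_id, meets_hr, meets_ir)
}

#' Stratify by the ESGE criterion
#'
#' High risk: ascending cholangitis or stone on imaging. Intermediate
#' risk: abnormal liver function tests or dilated duct. Low risk: none of
#' these factors present. Returned in the same two readings as
#' [asge_stratify()]. The ESGE high-risk disjunction is a subset of the
#' ASGE one, so `meets_hr` here implies ASGE `meets_hr`.
#'
#' @inheritParams sages_stratify
#' @return A tibble in the same shape as [asge_stratify()].
#' @export
esge_stratify <- function(factors) {
  validate_factors(factors)
  meets_hr <- factors$cholangitis | factors$imaging_stone
  meets_ir <- factors$lft_abnormal | factors$dilated_cbd
  assignment_tibble("ESGE", factors$patient_id, meets_hr, meets_ir)
}

#' Apply a risk criterion to a whole cohort
#'
#' Derives factors and assigns strata for one criterion, returning one
#' assignment row per patient in input order. For SAGES, which has no
#' published indicator reading, `meets_hr` is "two or more factors",
#' `meets_ir` is "at least one factor" and the exclusive stratum is the
#' usual 2/1/0 count rule, so the assignment shape is uniform across
#' criteria.
#'
#' @param cohort A patient cohort (see [read_cohort()] for the schema).
#' @param criterion One of `"sages"`, `"asge"`, `"esge"`.
#' @param thresholds A `cbd_thresholds` object.
#' @return A tibble with columns `patient_id`, `criterion`,
#'   `exclusive_stratum`, `meets_hr`, `meets_ir`, `meets_strict_lr`.
#' @examples
#' table(stratify_cohort(reconstruct_cohort(), "sages")$exclusive_stratum)
#' @export
stratify_cohort <- function(cohort,
                            criterion = c("sages", "asge", "esge"),
                            thresholds = criterion_thresholds()) {
  criterion <- match.arg(criterion)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  factors <- derive_factors(cohort, thresholds)
  switch(criterion,
    sages = {
      n_factors <- factors$imaging_stone + factors$dilated_cbd +
        factors$cholangitis + factors$tb_over_sages
      assignment_tibble("SAGES", factors$patient_id,
                        meets_hr = n_factors >= 2L,
                        meets_ir = n_factors >= 1L)
    },
    asge = asge_stratify(factors),
    esge = esge_stratify(factors)
  )
}
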