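#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of the reference cohort:
#' two-thirds stone prevalence, ultrasound detecting 95% of true stones
#' with a 30% false-call rate in stone-free patients, cholangitis in about
#' 18% of stone carriers (and only in stone carriers), duct diameters
#' normal around 11 mm (stone) vs 7 mm (no stone), log-normal total
#' bilirubin centred near 3.5 vs 1.5 mg/dL, and a 30% chance of a
#' non-bilirubin liver-test derangement.
#'
#' @param n Cohort size.
#' @param prevalence Fraction with a true CBD stone.
#' @param p_imaging_given_stone,p_imaging_given_no_stone Probability that
#'   imaging shows a stone, conditional on true stone status.
#' @param p_cholangitis_given_stone Probability of ascending cholangitis
#'   among stone carriers; stone-free patients never have it.
#' @param cbd_mm_stone,cbd_mm_no_stone Length-2 vectors `c(mean, sd)` of
#'   the normal duct-diameter distribution (mm) by stone status; draws are
#'   floored at 2 mm.
#' @param tb_mgdl_stone,tb_mgdl_no_stone Length-2 vectors
#'   `c(meanlog, sdlog)` of the log-normal total-bilirubin distribution
#'   (mg/dL) by stone status.
#' @param p_lft_abnormal_extra Probability of a liver-test derangement not
#'   driven by bilirubin (e.g. transaminases); combined with the bilirubin
#'   criterion by disjunction.
#' @param age_mean,age_sd Normal age distribution (years), truncated to at
#'   least 18.
#' @param seed Integer seed; identical seed and parameters give an
#'   identical cohort.
#' @return A `cbd_sim_params` object (named list).
#' @export
simulation_params <- function(n = 90,
                              prevalence = 60 / 90,
                              p_imaging_given_stone = 0.95,
                              p_imaging_given_no_stone = 0.30,
                              p_cholangitis_given_stone = 11 / 60,
                              cbd_mm_stone = c(11, 2.7),
                              cbd_mm_no_stone = c(7, 3),
                              tb_mgdl_stone = c(1.25, 0.6),
                              tb_mgdl_no_stone = c(0.4, 0.7),
                              p_lft_abnormal_extra = 0.30,
                              age_mean = 45.2,
                              age_sd = 14.9,
                              seed = 1L) {
  p <- list(n = as.integer(n), prevalence = prevalence,
            p_imaging_given_stone = p_imaging_given_stone,
            p_imaging_given_no_stone = p_imaging_given_no_stone,
            p_cholangitis_given_stone = p_cholangitis_given_stone,
            cbd_mm_stone = as.numeric(cbd_mm_stone),
            cbd_mm_no_stone = as.numeric(cbd_mm_no_stone),
            tb_mgdl_stone = as.numeric(tb_mgdl_stone),
            tb_mgdl_no_stone = as.numeric(tb_mgdl_no_stone),
            p_lft_abnormal_extra = p_lft_abnormal_extra,
            age_mean = age_mean, age_sd = age_sd,
            seed = as.integer(seed))
  if (p$n <= 0L) stop("n must be positive", call. = FALSE)
  for (nm in c("prevalence", "p_imaging_given_stone",
               "p_imaging_given_no_stone", "p_cholangitis_given_stone",
               "p_lft_abnormal_extra")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("cbd_mm_stone", "cbd_mm_no_stone", "tb_mgdl_stone",
               "tb_mgdl_no_stone")) {
    v <- p[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[2] <= 0) {
      stop("`", nm, "` must be c(location, scale) with positive scale",
           call. = FALSE)
    }
  }
  if (p$age_sd <= 0) stop("age_sd must be positive", call. = FALSE)
  structure(p, class = "cbd_sim_params")
}

#' Read simulation parameters from a YAML or JSON file
#'
#' @param path Path to a flat mapping whose keys mirror the arguments of
#'   [simulation_params()].
#' @return A `cbd_sim_params` object.
#' @export
read_simulation_params <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(simulation_params))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown simulation parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_params, vals)
}

# Run code under a local RNG state so simulation does not disturb the
# caller's random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a synthetic patient cohort
#'
#' Seeded generative model for property testing and power exploration.
#' True stone status is Bernoulli with the stated prevalence; imaging,
#' cholangitis (stone carriers only), duct diameter, bilirubin, extra
#' liver-test derangement, age and sex are then drawn conditionally on it
#' as described in [simulation_params()]. `lft_abnormal` is the
#' disjunction of bilirubin above the SAGES reference cut-off and the
#' extra derangement.
#'
#' @param params A `cbd_sim_params` object.
#' @param seed Optional integer overriding `params$seed`.
#' @param thresholds Thresholds used to tie `lft_abnormal` to bilirubin.
#' @return A cohort tibble in the [read_cohort()] schema.
#' @examples
#' cohort <- simulate_cohort(simulation_params(n = 200, seed = 42))
#' mean(cohort$ercp_stone)
#' @export
simulate_cohort <- function(params = simulation_params(), seed = NULL,
                            thresholds = criterion_thresholds()) {
  stopifnot(inherits(params, "cbd_sim_params"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  n <- params$n
  with_local_seed(params$seed, {
    stone <- runif(n) < params$prevalence
    p_img <- ifelse(stone, params$p_imaging_given_stone,
                    params$p_imaging_given_no_stone)
    imaging <- runif(n) < p_img
    cholangitis <- stone & runif(n) < params$p_cholangitis_given_stone
    cbd <- ifelse(stone,
                  rnorm(n, params$cbd_mm_stone[1], params$cbd_mm_stone[2]),
                  rnorm(n, params$cbd_mm_no_stone[1], params$cbd_mm_no_stone[2]))
    cbd <- pmax(cbd, 2)
    tb <- ifelse(stone,
                 rlnorm(n, params$tb_mgdl_stone[1], params$tb_mgdl_stone[2]),
                 rlnorm(n, params$tb_mgdl_no_stone[1], params$tb_mgdl_no_stone[2]))
    lft_extra <- runif(n) < params$p_lft_abnormal_extra
    age <- pmax(round(rnorm(n, params$age_mean, params$age_sd)), 18)
    sex <- ifelse(runif(n) < 0.5, "male", "female")
    tibble(
      patient_id = sprintf("S%05d", seq_len(n)),
      age = as.numeric(age),
      sex = sex,
      total_bilirubin_mgdl = round(tb, 2),
      lft_abnormal = round(tb, 2) > thresholds$sages_tb_mgdl | lft_extra,
      cbd_diameter_mm = round(cbd, 1),
      stone_on_imaging = imaging,
      cholangitis = cholangitis,
      ercp_stone = stone
    )
  })
}
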