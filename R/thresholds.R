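#' Decision thresholds for the three risk criteria
#'
#' Bundles the numeric cut-offs the SAGES, ASGE 2019 and ESGE rules compare
#' patient fields against. All comparisons made by [derive_factors()] are
#' strict (`>`): a common bile duct measuring exactly 6 mm is *not* dilated,
#' a total bilirubin of exactly 1.7 mg/dL is *not* elevated.
#'
#' @param cbd_dilated_mm Common bile duct diameter (mm) above which the duct
#'   counts as dilated on ultrasound. Default 6.
#' @param sages_tb_mgdl Total bilirubin (mg/dL) above which the SAGES
#'   bilirubin factor is present. Default 1.7.
#' @param asge_tb_mgdl Total bilirubin (mg/dL) above which the ASGE
#'   high-risk bilirubin-plus-dilated-duct factor applies. Default 4.
#' @param asge_age_years Age (years) above which the ASGE intermediate-risk
#'   age factor is present. Default 55.
#'
#' @return An object of class `cbd_thresholds`: a named list of the four
#'   validated cut-offs.
#' @examples
#' criterion_thresholds()
#' criterion_thresholds(cbd_dilated_mm = 8)
#' @seealso [read_thresholds()] to load cut-offs from a YAML or JSON file.
#' @export
criterion_thresholds <- function(cbd_dilated_mm = 6,
                                 sages_tb_mgdl = 1.7,
                                 asge_tb_mgdl = 4,
                                 asge_age_years = 55) {
  th <- list(
    cbd_dilated_mm = as.numeric(cbd_dilated_mm),
    sages_tb_mgdl  = as.numeric(sages_tb_mgdl),
    asge_tb_mgdl   = as.numeric(asge_tb_mgdl),
    asge_age_years = as.numeric(asge_age_years)
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("threshold `", nm, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (th$sages_tb_mgdl >= th$asge_tb_mgdl) {
    stop("`sages_tb_mgdl` must be below `asge_tb_mgdl` (the ASGE bilirubin ",
         "cut-off is the stricter one)", call. = FALSE)
  }
  structure(th, class = "cbd_thresholds")
}

#' Read criterion thresholds from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [criterion_thresholds()]; absent keys keep their defaults, unknown keys
#' are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cbd_thresholds` object.
#' @export
read_thresholds <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("threshold file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(criterion_thresholds))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown threshold field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(criterion_thresholds, vals)
}

#' @export
print.cbd_thresholds <- function(x, ...) {
  cat("Risk-criterion thresholds (all strict '>'):\n")
  cat(sprintf("  dilated CBD        : > %g mm\n", x$cbd_dilated_mm))
  cat(sprintf("  SAGES bilirubin    : > %g mg/dL\n", x$sages_tb_mgdl))
  cat(sprintf("  ASGE bilirubin     : > %g mg/dL (with dilated CBD)\n",
              x$asge_tb_mgdl))
  cat(sprintf("  ASGE age           : > %g years\n", x$asge_age_years))
  invisible(x)
}
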