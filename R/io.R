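#' Read a patient cohort from CSV
#'
#' Expects one row per patient with the canonical header
#' `patient_id,age,sex,total_bilirubin_mgdl,lft_abnormal,cbd_diameter_mm,stone_on_imaging,cholangitis,ercp_stone`.
#' Boolean columns are coded 0/1; empty cells are missing. Unknown extra
#' columns are preserved verbatim after the required ones. Malformed
#' boolean cells and invariant violations are reported with the offending
#' row and column; a missing required column is a hard error.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param validate Run [validate_cohort()] on the result (default TRUE).
#' @return A cohort tibble.
#' @seealso [write_cohort()] for the inverse; the pair round-trips
#'   exactly.
#' @export
read_cohort <- function(path, validate = TRUE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- as_tibble(raw)[, c(cohort_columns(),
                            setdiff(names(raw), cohort_columns()))]
  if (nrow(raw) == 0L) return(raw[0, ])

  parse_bool <- function(x, col) {
    x <- trimws(x)
    bad <- !(x %in% c("0", "1", ""))
    if (any(bad)) {
      stop("column `", col, "`: invalid boolean cell(s) ",
           paste(sprintf("'%s' (row %d)", x[bad], which(bad) + 1L),
                 collapse = ", "),
           "; expected 0 or 1", call. = FALSE)
    }
    out <- rep(NA, length(x))
    out[x == "1"] <- TRUE
    out[x == "0"] <- FALSE
    out
  }
  parse_num <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & x != ""
    if (any(bad)) {
      stop("column `", col, "`: non-numeric cell(s) ",
           paste(sprintf("'%s' (row %d)", x[bad], which(bad) + 1L),
                 collapse = ", "), call. = FALSE)
    }
    out
  }
  cohort <- raw
  cohort$age <- parse_num(raw$age, "age")
  cohort$total_bilirubin_mgdl <- parse_num(raw$total_bilirubin_mgdl,
                                           "total_bilirubin_mgdl")
  cohort$cbd_diameter_mm <- parse_num(raw$cbd_diameter_mm, "cbd_diameter_mm")
  for (col in cohort_logical_columns()) {
    cohort[[col]] <- parse_bool(raw[[col]], col)
  }
  if (validate) cohort <- validate_cohort(cohort)
  cohort
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans are written as 0/1, numerics in
#' full precision, extra columns after the canonical ones. Output is
#' deterministic for a given cohort.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort[, c(cohort_columns(),
                                  setdiff(names(cohort), cohort_columns()))])
  for (col in cohort_logical_columns()) {
    out[[col]] <- as.integer(out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
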