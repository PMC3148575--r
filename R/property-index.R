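#' Derive per-unit residential values from property assessment records
#'
#' Computes the residential value index in its continuous form: the average
#' monetary value of one residential unit in the building each subject
#' inhabits. The commercial share of the building's assessed value is removed
#' and the remainder divided by the number of residential units. Condominium
#' records already carry an individual per-unit assessment, so they are taken
#' at face value (no commercial subtraction) and treated as a single unit.
#'
#' Records that cannot be assigned a residential value are not dropped
#' silently: they are returned with an `exclusion_reason` and an `NA`
#' `unit_value`, so that input rows are always conserved
#' (included + excluded = input).
#'
#' @param data A data frame of assessment records, one row per subject, with
#'   columns `subject_id`, `total_value` (assessed building value, CAD >= 0),
#'   `commercial_proportion` (fraction of building area identified as
#'   commercial, in \[0, 1\]; `NA` is interpreted as 0 with a warning),
#'   `n_residential_units` (integer >= 0) and `is_condominium` (logical).
#'   Extra columns are ignored.
#' @return A tibble with columns `subject_id`, `unit_value` (CAD, `NA` when
#'   excluded) and `exclusion_reason` (`NA` when included). Reason codes:
#'   `"no residential units"`, `"fully commercial"`, `"zero assessed value"`.
#' @examples
#' recs <- tibble::tibble(
#'   subject_id = c("s1", "s2", "s3"),
#'   total_value = c(100000, 200000, 150000),
#'   commercial_proportion = c(0, 0.25, 0.10),
#'   n_residential_units = c(1L, 3L, 0L),
#'   is_condominium = c(FALSE, FALSE, TRUE)
#' )
#' residential_unit_value(recs)
#' @export
residential_unit_value <- function(data) {
  required <- c(
    "subject_id", "total_value", "commercial_proportion",
    "n_residential_units", "is_condominium"
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  tv <- as.double(data$total_value)
  cp <- as.double(data$commercial_proportion)
  nu <- data$n_residential_units
  condo <- data$is_condominium

  if (anyNA(tv) || any(!is.finite(tv)) || any(tv < 0)) {
    abort("`total_value` must be finite and non-negative for every record.")
  }
  if (anyNA(condo)) {
    abort("`is_condominium` must be TRUE or FALSE for every record.")
  }
  if (anyNA(cp)) {
    warn(paste0(
      sum(is.na(cp)), " record(s) with missing `commercial_proportion`; ",
      "treated as 0 (no commercial space)."
    ))
    cp[is.na(cp)] <- 0
  }
  if (any(!is.finite(cp)) || any(cp < 0 | cp > 1)) {
    abort("`commercial_proportion` must lie in [0, 1].")
  }
  if (anyNA(nu) || any(nu < 0) || any(nu != trunc(nu))) {
    abort("`n_residential_units` must be a non-negative integer.")
  }

  value <- ifelse(condo, tv, tv * (1 - cp) / nu)

  reason <- rep(NA_character_, length(tv))
  reason[!condo & nu == 0] <- "no residential units"
  reason[is.na(reason) & !condo & cp >= 1] <- "fully commercial"
  reason[is.na(reason) & tv == 0] <- "zero assessed value"
  value[!is.na(reason)] <- NA_real_

  tibble(
    subject_id = data$subject_id,
    unit_value = value,
    exclusion_reason = reason
  )
}

#' Read property assessment records from a CSV file
#'
#' Expects the documented input schema: `building_id`, `total_value`,
#' `commercial_proportion`, `n_residential_units`, `is_condominium`,
#' `postal_code`, `subject_id`. Decimal point `"."`, no thousands separators.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of property records.
#' @export
read_property_records <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      building_id = readr::col_character(),
      total_value = readr::col_double(),
      commercial_proportion = readr::col_double(),
      n_residential_units = readr::col_integer(),
      is_condominium = readr::col_logical(),
      postal_code = readr::col_character(),
      subject_id = readr::col_character()
    )
  )
}

#' Write per-unit residential values to CSV
#'
#' @param unit_values A tibble as returned by [residential_unit_value()].
#' @param path Output file path.
#' @return `unit_values`, invisibly.
#' @export
write_unit_values <- function(unit_values, path) {
  out <- dplyr::mutate(
    unit_values,
    exclusion_reason = dplyr::coalesce(.data$exclusion_reason, "")
  )
  readr::write_csv(out, path)
  invisible(unit_values)
}
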