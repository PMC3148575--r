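#' Read the pipeline's subject and census-lookup input files
#'
#' `read_subjects()` expects `subject_id`, `income_band`, `postal_code` and
#' optional stratification columns; `read_census_lookup()` expects
#' `postal_code` and `census_income` (one row per postal code).
#'
#' @param path Path to a delimited text file.
#' @return A tibble.
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    postal_code = readr::col_character(),
    .default = readr::col_guess()
  ))
}

#' @rdname read_subjects
#' @export
read_census_lookup <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    postal_code = readr::col_character(),
    census_income = readr::col_double()
  ))
}

#' Published summary tables from the Montreal indicator comparison
#'
#' Summary tables reported by a Montreal case-control analysis (N = 676)
#' that compared a residential value index and census-tract median income
#' against self-reported household income, each in five categories:
#' the marginal frequency distributions of the three indicators (overall
#' and by sex) and the signed category-difference distributions with tails
#' lumped at three categories. These are the published inputs from which
#' kappa statistics can be reconstructed with [kappa_from_summaries()] and
#' [weighted_kappa_bounds()]; the full cross-tabulations were not
#' published.
#'
#' @return A list with tibbles `marginals` (indicator, category, band,
#'   pct_male, pct_female, pct_total) and `differences` (comparison,
#'   difference, count, pct), and the analysis-sample size `n`.
#' @examples
#' tabs <- montreal_income_tables()
#' self <- tabs$marginals$pct_total[tabs$marginals$indicator ==
#'                                    "self_report"] / 100
#' @export
montreal_income_tables <- function() {
  extdata <- function(f) {
    system.file("extdata", f, package = "matcirc", mustWork = TRUE)
  }
  marginals <- readr::read_csv(
    extdata("montreal_marginals.csv"),
    col_types = readr::cols(
      indicator = readr::col_character(),
      category = readr::col_integer(),
      band = readr::col_character(),
      pct_male = readr::col_double(),
      pct_female = readr::col_double(),
      pct_total = readr::col_double()
    )
  )
  differences <- readr::read_csv(
    extdata("montreal_differences.csv"),
    col_types = readr::cols(
      comparison = readr::col_character(),
      difference = readr::col_character(),
      count = readr::col_integer(),
      pct = readr::col_double()
    )
  )
  list(marginals = marginals, differences = differences, n = 676L)
}
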