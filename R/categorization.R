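#' Reference marginal distributions for five income categories
#'
#' The marginal distribution of self-reported household income used as the
#' categorization reference. `"analysis"` is the analysis-sample distribution
#' at one decimal (30.2/24.1/21.0/12.6/12.1 percent); `"rounded"` is the
#' whole-percent version (30/24/21/13/12).
#'
#' @param preset `"analysis"` (default) or `"rounded"`.
#' @return A numeric vector of 5 proportions summing to 1.
#' @export
reference_marginals <- function(preset = c("analysis", "rounded")) {
  preset <- arg_match(preset)
  switch(preset,
    analysis = c(0.302, 0.241, 0.210, 0.126, 0.121),
    rounded = c(0.30, 0.24, 0.21, 0.13, 0.12)
  )
}

validate_marginals <- function(p, arg = "reference") {
  if (!is.numeric(p) || length(p) < 2) {
    abort(sprintf("`%s` must be a numeric vector of length >= 2.", arg))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort(sprintf("`%s` proportions must lie in [0, 1].", arg))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` proportions must sum to 1 (within 1e-9).", arg))
  }
  p
}

#' Construct an ordinal category scheme from explicit cutoffs
#'
#' A scheme maps a continuous value to one of `k = length(cutoffs) + 1`
#' ordered categories using upper-inclusive intervals: values less than or
#' equal to the first cutoff fall in category 1, values above the last cutoff
#' in category `k`. This reproduces the printed interval convention
#' "<= $42,102; $42,103-$66,629; ...".
#'
#' @param cutoffs Strictly increasing numeric vector of k - 1 boundaries.
#' @return An object of class `"category_scheme"`.
#' @examples
#' residential <- category_scheme(c(42102, 66629, 94975, 133176))
#' assign_category(c(42102, 42103), residential)
#' @export
category_scheme <- function(cutoffs) {
  if (!is.numeric(cutoffs) || length(cutoffs) < 1) {
    abort("`cutoffs` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(cutoffs))) {
    abort("`cutoffs` must be finite.")
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    abort("`cutoffs` must be strictly increasing.")
  }
  structure(
    list(k = length(cutoffs) + 1L, cutoffs = as.double(cutoffs),
         boundary_rule = "upper-inclusive"),
    class = "category_scheme"
  )
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> ", x$k, " categories, ", x$boundary_rule, "\n",
      sep = "")
  lab <- format(x$cutoffs, big.mark = ",", trim = TRUE)
  cat("  1: <= ", lab[1], "\n", sep = "")
  if (x$k > 2) {
    for (i in seq_len(x$k - 2)) {
      cat("  ", i + 1, ": ", lab[i], " < x <= ", lab[i + 1], "\n", sep = "")
    }
  }
  cat("  ", x$k, ": > ", lab[x$k - 1], "\n", sep = "")
  invisible(x)
}

#' Demarcate category boundaries so marginals match a reference distribution
#'
#' Chooses cutoffs as empirical quantiles of `values` at the cumulative
#' reference proportions, so that categorizing `values` with the resulting
#' scheme approximates the reference marginal distribution. This is how the
#' continuous residential value index and census income are aligned with the
#' observed distribution of self-reported income before agreement is
#' assessed.
#'
#' Inverse-empirical-CDF (type 1) quantiles are used, so every cutoff is an
#' observed value and the upper-inclusive interval convention is exactly
#' reproducible; for tie-free samples the achieved category proportions
#' differ from the reference by at most 1/n. Other quantile definitions
#' would shift category counts by at most one subject.
#'
#' @param values Non-empty finite numeric vector (e.g. per-unit residential
#'   values in CAD).
#' @param reference Numeric vector of k proportions summing to 1; defaults to
#'   [reference_marginals()].
#' @return A [category_scheme()] with `k - 1` cutoffs.
#' @examples
#' sch <- reference_marginal_cutoffs(1:100, reference_marginals("rounded"))
#' table(assign_category(1:100, sch))
#' @export
reference_marginal_cutoffs <- function(values,
                                       reference = reference_marginals()) {
  reference <- validate_marginals(reference)
  k <- length(reference)
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("`values` must be non-empty and finite.")
  }
  if (length(values) < k) {
    abort(sprintf(
      "insufficient data: %d values cannot support %d categories.",
      length(values), k
    ))
  }
  if (length(unique(values)) == 1) {
    abort("all values identical: category scheme is degenerate.")
  }
  probs <- cumsum(reference)[-k]
  # inverse empirical CDF (type-1 quantile): cutoff j is the ceil(n p_j)-th
  # order statistic; the epsilon guards against cumsum floating-point noise
  # pushing an exactly-integer n * p up one order statistic
  xs <- sort(values)
  n <- length(xs)
  idx <- pmin(pmax(ceiling(n * probs - 1e-9), 1), n)
  cuts <- xs[idx]
  if (anyDuplicated(cuts)) {
    warn(paste0(
      "ties in `values` leave some categories empty; ",
      "duplicated cutoffs collapsed (fewer than ", k, " categories)."
    ))
    cuts <- unique(cuts)
  }
  category_scheme(cuts)
}

#' Assign continuous values to ordinal categories
#'
#' Applies the upper-inclusive interval convention of a
#' [category_scheme()]: `x <= cutoffs[1]` is category 1 and ties at a cutoff
#' go to the lower category. Assignment is monotone non-decreasing in `x`
#' and the bottom/top categories are unbounded.
#'
#' @param x Finite numeric vector.
#' @param scheme A [category_scheme()].
#' @return Integer vector of categories in `1..k`.
#' @export
assign_category <- function(x, scheme) {
  if (!inherits(scheme, "category_scheme")) {
    abort("`scheme` must be a category_scheme.")
  }
  if (any(!is.finite(x))) {
    abort("`x` must be finite.")
  }
  findInterval(x, scheme$cutoffs, left.open = TRUE) + 1L
}

#' Default mapping from income answer bands to five ordered categories
#'
#' The questionnaire's answer bands are collapsed to five income categories.
#' The default maps the five published band labels to categories 1 (lowest)
#' through 5 (highest); studies with a finer band vocabulary supply their own
#' named vector collapsing bands into these five categories.
#'
#' @return A named integer vector: band label -> category.
#' @export
income_band_mapping <- function() {
  c(
    "< $20,000" = 1L,
    "$20,000-$29,999" = 2L,
    "$30,000-$49,999" = 3L,
    "$50,000-$69,999" = 4L,
    ">= $70,000" = 5L
  )
}

#' Collapse income answer bands to five ordered categories
#'
#' @param band Character vector of answer-band labels.
#' @param mapping Named integer vector mapping every admissible band label to
#'   a category in `1..5`; defaults to [income_band_mapping()].
#' @return Integer vector of categories.
#' @examples
#' collapse_income_bands(c("< $20,000", ">= $70,000"))
#' @export
collapse_income_bands <- function(band, mapping = income_band_mapping()) {
  if (is.null(names(mapping)) || anyNA(mapping) ||
      any(mapping < 1 | mapping != trunc(mapping))) {
    abort("`mapping` must be a named vector of positive integer categories.")
  }
  out <- unname(mapping[match(band, names(mapping))])
  bad <- !is.na(band) & is.na(out)
  if (any(bad)) {
    abort(paste0(
      "income band(s) not in mapping: ",
      paste(unique(band[bad]), collapse = ", ")
    ))
  }
  as.integer(out)
}

#' Serialize a category scheme to JSON for provenance
#'
#' @param scheme A [category_scheme()].
#' @param path Output file path.
#' @return `scheme`, invisibly.
#' @export
write_category_scheme <- function(scheme, path) {
  if (!inherits(scheme, "category_scheme")) {
    abort("`scheme` must be a category_scheme.")
  }
  jsonlite::write_json(
    list(k = scheme$k, cutoffs = scheme$cutoffs,
         boundary_rule = scheme$boundary_rule),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(scheme)
}

#' Read a category scheme from its JSON serialization
#'
#' @param path Path to a JSON file written by [write_category_scheme()].
#' @return A [category_scheme()].
#' @export
read_category_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  category_scheme(obj$cutoffs)
}
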