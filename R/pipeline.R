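#' Run the full indicator-agreement analysis
#'
#' End-to-end pipeline: derives the residential value index from the
#' property records, joins census-tract median income by postal code,
#' restricts to subjects with all three indicators available (the analysis
#' sample), categorizes the two continuous indicators by quantile matching
#' to the reference marginal distribution, and computes, for each proxy
#' against self-reported income: the marginal tables, the signed
#' category-difference distribution with lumped tails, concordance
#' proportions, Spearman correlation, and overall and linearly weighted
#' kappa with confidence intervals.
#'
#' @param subjects Data frame with columns `subject_id`, `income_band`
#'   (integer category 1..5, or character answer-band labels collapsed via
#'   `income_mapping`; `NA` = nonresponse), `postal_code`, and any
#'   stratification columns.
#' @param property Data frame of assessment records keyed by `subject_id`
#'   (see [residential_unit_value()]).
#' @param census_lookup Data frame with `postal_code` and `census_income`
#'   (tract median household income).
#' @param reference Category proportions used to demarcate cutoffs for the
#'   continuous indicators. The default (`NULL`) uses the observed
#'   distribution of self-reported income in the analysis sample, which is
#'   the usual choice when the self-report is the comparison base; fixed
#'   presets are available via [reference_marginals()].
#' @param income_mapping Band-label mapping for character `income_band`
#'   (default [income_band_mapping()]).
#' @param lump_at Lumping threshold for the difference distribution
#'   (default 3).
#' @param ci,conf_level,boot_reps,seed Confidence-interval options passed to
#'   [cohen_kappa()] and [weighted_kappa()].
#' @param schemes Optional list with `residential` and `census`
#'   [category_scheme()]s to reuse (e.g. pooled schemes in stratified
#'   sensitivity analyses) instead of deriving them from this sample.
#' @return An object of class `"analysis_report"`; see [tidy()],
#'   [glance()] and [autoplot()] methods. Key elements: `accounting`
#'   (indicator availability and exclusion ledger), `marginals`,
#'   `agreement`, `concordance`, per-pair cross-tabs and difference
#'   distributions, and the category `schemes` used.
#' @export
run_analysis <- function(subjects, property, census_lookup,
                         reference = NULL,
                         income_mapping = income_band_mapping(),
                         lump_at = 3L,
                         ci = c("asymptotic", "bootstrap"),
                         conf_level = 0.95, boot_reps = 2000, seed = NULL,
                         schemes = NULL) {
  ci <- arg_match(ci)
  for (col in c("subject_id", "income_band", "postal_code")) {
    if (!col %in% names(subjects)) {
      abort(sprintf("`subjects` is missing column `%s`.", col))
    }
  }
  if (!all(c("postal_code", "census_income") %in% names(census_lookup))) {
    abort("`census_lookup` needs columns postal_code and census_income.")
  }
  if (anyDuplicated(census_lookup$postal_code)) {
    abort("`census_lookup` must have one row per postal code.")
  }

  income_cat <- subjects$income_band
  if (is.character(income_cat)) {
    known <- !is.na(income_cat)
    mapped <- rep(NA_integer_, length(income_cat))
    mapped[known] <- collapse_income_bands(income_cat[known], income_mapping)
    income_cat <- mapped
  }
  if (any(income_cat < 1, na.rm = TRUE) ||
      any(income_cat != trunc(income_cat), na.rm = TRUE)) {
    abort("`income_band` categories must be positive integers.")
  }

  uv <- residential_unit_value(property)
  d <- subjects |>
    mutate(income_cat = as.integer(income_cat)) |>
    left_join(select(uv, "subject_id", "unit_value", "exclusion_reason"),
              by = "subject_id") |>
    left_join(census_lookup, by = "postal_code")

  exclusions <- tibble(
    subject_id = d$subject_id,
    reason = dplyr::case_when(
      is.na(d$income_cat) ~ "income not reported",
      is.na(d$unit_value) & !is.na(d$exclusion_reason) ~ d$exclusion_reason,
      is.na(d$unit_value) ~ "no property record",
      is.na(d$census_income) ~ "no census match",
      TRUE ~ NA_character_
    )
  ) |> filter(!is.na(.data$reason))

  accounting <- tibble(
    quantity = c(
      "subjects", "income available", "residential value available",
      "census income available", "complete triples"
    ),
    n = c(
      nrow(d),
      sum(!is.na(d$income_cat)),
      sum(!is.na(d$unit_value)),
      sum(!is.na(d$census_income)),
      sum(!is.na(d$income_cat) & !is.na(d$unit_value) &
            !is.na(d$census_income))
    )
  )

  complete <- filter(
    d, !is.na(.data$income_cat), !is.na(.data$unit_value),
    !is.na(.data$census_income)
  )
  if (nrow(complete) == 0) {
    abort("no complete triples: no subject has all three indicators.")
  }

  k <- if (is.null(reference)) {
    max(complete$income_cat, 5L)
  } else {
    length(validate_marginals(reference))
  }
  ref <- if (is.null(reference)) {
    as.vector(table(factor(complete$income_cat, levels = 1:k))) /
      nrow(complete)
  } else {
    reference
  }

  if (is.null(schemes)) {
    schemes <- list(
      residential = reference_marginal_cutoffs(complete$unit_value, ref),
      census = reference_marginal_cutoffs(complete$census_income, ref)
    )
  }

  complete <- mutate(
    complete,
    residential_cat = assign_category(.data$unit_value,
                                      schemes$residential),
    census_cat = assign_category(.data$census_income, schemes$census)
  )

  pair_stats <- function(proxy_cat, pair_label) {
    tab <- new_cross_tab_from_pairs(complete$income_cat, proxy_cat, k = k)
    dd <- difference_distribution(tab, lump_at = lump_at)
    kap <- cohen_kappa(tab, ci = ci, conf_level = conf_level,
                      boot_reps = boot_reps, seed = seed)
    kw <- weighted_kappa(tab, ci = ci, conf_level = conf_level,
                         boot_reps = boot_reps, seed = seed)
    rho <- spearman_ordinal(
      tibble(a = complete$income_cat, b = proxy_cat), .data$a, .data$b
    )
    list(tab = tab, dd = dd, kappa = kap, kappa_w = kw, spearman = rho,
         label = pair_label)
  }

  pairs <- list(
    residential = pair_stats(complete$residential_cat,
                             "residential value index vs self-report"),
    census = pair_stats(complete$census_cat,
                        "census income vs self-report")
  )

  marginals <- purrr::map_dfr(
    list(self_report = complete$income_cat,
         residential = complete$residential_cat,
         census = complete$census_cat),
    function(v) {
      tibble(category = 1:k,
             n = as.vector(table(factor(v, levels = 1:k)))) |>
        mutate(pct = 100 * n / sum(n))
    },
    .id = "indicator"
  )

  agreement <- purrr::map_dfr(pairs, function(p) {
    tibble(
      pair = p$label,
      spearman = p$spearman,
      kappa = p$kappa$estimate,
      kappa_low = p$kappa$conf_low,
      kappa_high = p$kappa$conf_high,
      kappa_w = p$kappa_w$estimate,
      kappa_w_low = p$kappa_w$conf_low,
      kappa_w_high = p$kappa_w$conf_high
    )
  })

  concordance <- purrr::map_dfr(pairs, function(p) {
    tibble(
      pair = p$label,
      perfect = concordance_within(p$dd, 0L),
      within_one = if (lump_at > 1) concordance_within(p$dd, 1L) else
        NA_real_
    )
  })

  structure(
    list(
      n_input = nrow(d),
      n_analysis = nrow(complete),
      accounting = accounting,
      exclusions = exclusions,
      marginals = marginals,
      schemes = schemes,
      pairs = pairs,
      agreement = agreement,
      concordance = concordance,
      settings = list(lump_at = lump_at, ci = ci, conf_level = conf_level,
                      reference = ref, k = k)
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> analysis sample n = ", x$n_analysis,
      " of ", x$n_input, " subjects\n", sep = "")
  for (p in x$pairs) {
    cc <- x$concordance[x$concordance$pair == p$label, ]
    cat("\n", p$label, "\n", sep = "")
    cat(sprintf("  perfect concordance %.1f%%", 100 * cc$perfect))
    if (!is.na(cc$within_one)) {
      cat(sprintf(", within one category %.1f%%", 100 * cc$within_one))
    }
    cat("\n")
    cat(sprintf(
      "  Spearman %.2f | kappa %.2f (%.2f - %.2f) | weighted kappa %.2f (%.2f - %.2f)\n",
      p$spearman, p$kappa$estimate, p$kappa$conf_low, p$kappa$conf_high,
      p$kappa_w$estimate, p$kappa_w$conf_low, p$kappa_w$conf_high
    ))
  }
  invisible(x)
}

#' Tidy an analysis report
#'
#' @param x An `"analysis_report"`.
#' @param ... Unused.
#' @return The agreement tibble: one row per indicator pair with Spearman
#'   correlation and both kappas with confidence limits.
#' @method tidy analysis_report
#' @export
tidy.analysis_report <- function(x, ...) x$agreement

#' Glance at an analysis report
#'
#' @param x An `"analysis_report"`.
#' @param ... Unused.
#' @return A one-row tibble with sample accounting and settings.
#' @method glance analysis_report
#' @export
glance.analysis_report <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_analysis = x$n_analysis,
    k = x$settings$k,
    lump_at = x$settings$lump_at,
    ci_method = x$settings$ci
  )
}

#' Plot the agreement estimates of an analysis report
#'
#' Point estimates with confidence intervals for the overall and weighted
#' kappa of each indicator pair.
#'
#' @param object An `"analysis_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot analysis_report
#' @export
autoplot.analysis_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$agreement,
    cols = c("kappa", "kappa_w"),
    names_to = "statistic", values_to = "estimate"
  ) |>
    mutate(
      low = ifelse(.data$statistic == "kappa", .data$kappa_low,
                   .data$kappa_w_low),
      high = ifelse(.data$statistic == "kappa", .data$kappa_high,
                    .data$kappa_w_high),
      statistic = ifelse(.data$statistic == "kappa", "overall kappa",
                         "weighted kappa")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$pair,
                                   colour = .data$statistic)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      height = 0.15, position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "chance-corrected agreement", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stratified sensitivity analyses
#'
#' Re-runs the full analysis within each level of a stratification column
#' (sex, case/control status, respondent type, interview-period flags, ...)
#' and summarizes how the weighted kappa moves relative to the pooled
#' estimate. Category schemes are derived once on the pooled analysis
#' sample and reused in every stratum, so subjects keep the same category
#' wherever they are analysed and the pooled cross-tab is the cell-wise sum
#' of the stratum cross-tabs.
#'
#' @inheritParams run_analysis
#' @param strata Column in `subjects` (tidy-select) defining the strata.
#' @param min_n Minimum analysis-sample size for a stratum; smaller strata
#'   are skipped with a warning (default 25).
#' @return An object of class `"strata_report"`: the pooled
#'   `"analysis_report"`, one report per retained stratum, and a
#'   `comparison` tibble of weighted kappas and their deltas vs pooled.
#' @export
run_strata <- function(subjects, property, census_lookup, strata,
                       min_n = 25, ...) {
  labels <- pull(subjects, {{ strata }})
  if (anyNA(labels)) {
    warn("subjects with a missing stratum label are dropped from strata.")
  }
  pooled <- run_analysis(subjects, property, census_lookup, ...)

  levels_ <- sort(unique(labels[!is.na(labels)]))
  reports <- list()
  for (lev in levels_) {
    sub <- subjects[!is.na(labels) & labels == lev, , drop = FALSE]
    rep_lev <- tryCatch(
      run_analysis(sub, property, census_lookup, ...,
                   schemes = pooled$schemes),
      error = function(e) NULL
    )
    if (is.null(rep_lev) || rep_lev$n_analysis < min_n) {
      warn(sprintf(
        "stratum '%s' skipped (fewer than %d analysable subjects).",
        as.character(lev), min_n
      ))
      next
    }
    reports[[as.character(lev)]] <- rep_lev
  }

  comparison <- purrr::map_dfr(names(reports), function(nm) {
    r <- reports[[nm]]
    ag <- r$agreement
    pooled_ag <- pooled$agreement
    tibble(
      stratum = nm,
      pair = ag$pair,
      n = r$n_analysis,
      kappa_w = ag$kappa_w,
      kappa_w_pooled = pooled_ag$kappa_w[match(ag$pair, pooled_ag$pair)],
      delta = ag$kappa_w -
        pooled_ag$kappa_w[match(ag$pair, pooled_ag$pair)]
    )
  })

  structure(
    list(pooled = pooled, strata = reports, comparison = comparison),
    class = "strata_report"
  )
}

#' @export
print.strata_report <- function(x, ...) {
  cat("<strata_report> pooled n = ", x$pooled$n_analysis, ", ",
      length(x$strata), " strata\n", sep = "")
  print(as.data.frame(x$comparison), digits = 3)
  invisible(x)
}

#' Tidy a stratified report
#'
#' @param x A `"strata_report"`.
#' @param ... Unused.
#' @return The stratum-vs-pooled weighted-kappa comparison tibble.
#' @method tidy strata_report
#' @export
tidy.strata_report <- function(x, ...) x$comparison

#' Write an analysis report to CSV and JSON files
#'
#' CSV tables are written at report precision; `report.json` keeps full
#' numeric precision, and the category schemes are serialized alongside for
#' provenance.
#'
#' @param report An `"analysis_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    agreement = file.path(dir, "agreement.csv"),
    marginals = file.path(dir, "marginals.csv"),
    differences = file.path(dir, "differences.csv"),
    accounting = file.path(dir, "accounting.csv"),
    json = file.path(dir, "report.json")
  )
  readr::write_csv(report$agreement, paths[["agreement"]])
  readr::write_csv(report$marginals, paths[["marginals"]])
  diffs <- purrr::map_dfr(report$pairs, function(p) {
    mutate(as_tibble(p$dd), pair = p$label)
  })
  readr::write_csv(diffs, paths[["differences"]])
  readr::write_csv(report$accounting, paths[["accounting"]])
  jsonlite::write_json(
    list(
      n_input = report$n_input,
      n_analysis = report$n_analysis,
      accounting = report$accounting,
      agreement = report$agreement,
      concordance = report$concordance,
      marginals = report$marginals,
      schemes = purrr::map(report$schemes, function(s) {
        list(k = s$k, cutoffs = s$cutoffs, boundary_rule = s$boundary_rule)
      }),
      settings = report$settings
    ),
    paths[["json"]],
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  for (nm in names(report$schemes)) {
    write_category_scheme(report$schemes[[nm]],
                          file.path(dir, paste0("scheme_", nm, ".json")))
  }
  invisible(paths)
}
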