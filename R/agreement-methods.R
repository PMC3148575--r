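#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ", x$method, "\n", sep = "")
  cat(sprintf("  estimate = %.2f", x$estimate))
  if (!is.na(x$conf_low)) {
    cat(sprintf(" (%d%% CI %.2f - %.2f, %s)",
                round(100 * x$conf_level), x$conf_low, x$conf_high,
                x$ci_method))
  }
  cat("\n")
  cat(sprintf("  P_obs = %.3f, P_exp = %.3f", x$p_obs, x$p_exp))
  if (!is.na(x$n)) cat(", n =", x$n)
  cat("\n")
  invisible(x)
}

#' Tidy an agreement result
#'
#' @param x An `"agreement_result"`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble(
    method = x$method,
    estimate = x$estimate,
    std.error = x$se,
    conf.low = x$conf_low,
    conf.high = x$conf_high
  )
}

#' Glance at an agreement result
#'
#' @param x An `"agreement_result"`.
#' @param ... Unused.
#' @return A one-row tibble with the agreement components and sample size.
#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble(
    p_obs = x$p_obs,
    p_exp = x$p_exp,
    conf.level = x$conf_level,
    ci.method = x$ci_method,
    n = x$n
  )
}

#' @export
print.kappa_bounds <- function(x, ...) {
  cat("<kappa_bounds> weighted kappa in [",
      sprintf("%.3f", x$lower), ", ", sprintf("%.3f", x$upper),
      "] (tails lumped at |d| >= ", x$lump_at, ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy weighted-kappa bounds
#'
#' @param x A `"kappa_bounds"` object.
#' @param ... Unused.
#' @return A one-row tibble with `lower`, `upper`, `p_exp`, `n`.
#' @method tidy kappa_bounds
#' @export
tidy.kappa_bounds <- function(x, ...) {
  tibble(lower = x$lower, upper = x$upper, p_exp = x$p_exp, n = x$n)
}

#' Plot a category-difference distribution
#'
#' Diverging bar chart of the proportion of subjects by signed category
#' difference; negative differences are underestimation of the row
#' (self-report) indicator by the column (proxy) indicator.
#'
#' @param object A `"diff_dist"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_dist
#' @export
autoplot.diff_dist <- function(object, ...) {
  d <- attr(object, "d")
  df <- as_tibble(object)
  df$side <- factor(
    ifelse(d < 0, "underestimation",
           ifelse(d > 0, "overestimation", "perfect")),
    levels = c("underestimation", "perfect", "overestimation")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference,
                                   y = .data$proportion,
                                   fill = .data$side)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "category difference (proxy - self-report)",
                  y = "subjects", fill = NULL) +
    ggplot2::theme_minimal()
}
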