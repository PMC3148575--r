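#' Cross-tabulate two ordinal classifications of the same subjects
#'
#' Builds the k x k joint count table underlying every agreement statistic.
#' Rows index the first classification (by convention self-reported income),
#' columns the second (the proxy indicator), so positive column-minus-row
#' differences mean the proxy overestimates self-report.
#'
#' @param data A data frame with one row per subject.
#' @param rows,cols Columns (tidy-select) holding integer categories in
#'   `1..k` for the row and column classification.
#' @param k Number of categories; defaults to the largest category observed.
#' @return An object of class `"cross_tab"`: a list with `counts` (k x k
#'   integer matrix), `n` and `k`.
#' @examples
#' d <- tibble::tibble(a = c(1, 2, 2), b = c(1, 2, 1))
#' cross_tabulate(d, a, b, k = 2)
#' @export
cross_tabulate <- function(data, rows, cols, k = NULL) {
  a <- pull(data, {{ rows }})
  b <- pull(data, {{ cols }})
  new_cross_tab_from_pairs(a, b, k)
}

new_cross_tab_from_pairs <- function(a, b, k = NULL) {
  if (length(a) == 0) {
    abort("cannot cross-tabulate zero subjects.")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("categories must be non-missing; filter to complete pairs first.")
  }
  if (any(a != trunc(a)) || any(b != trunc(b)) || any(a < 1) || any(b < 1)) {
    abort("categories must be positive integers.")
  }
  if (is.null(k)) k <- max(a, b)
  if (any(a > k) || any(b > k)) {
    abort(sprintf("categories out of range 1..%d.", k))
  }
  counts <- matrix(0L, k, k)
  tab <- table(factor(a, levels = 1:k), factor(b, levels = 1:k))
  counts[] <- as.integer(tab)
  as_cross_tab(counts)
}

#' Construct a cross_tab from a count matrix
#'
#' @param counts Square matrix of non-negative cell counts; rows are the
#'   first classification's categories, columns the second's.
#' @return A `"cross_tab"` object.
#' @export
as_cross_tab <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2) {
    abort("`counts` must be a square matrix with k >= 2.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  structure(
    list(counts = counts, n = sum(counts), k = nrow(counts)),
    class = "cross_tab"
  )
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("<cross_tab> ", x$k, " x ", x$k, ", n = ", x$n, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Distribution of signed category differences, with lumped tails
#'
#' Summarizes a cross-tabulation by the signed difference
#' `d = column category - row category`; positive values mean the column
#' (proxy) indicator overestimates the row (self-report) indicator.
#' Differences at or beyond `lump_at` in absolute value are merged into
#' "<= -lump_at" and ">= lump_at" tail bins, the form in which such
#' discrepancy tables are usually published.
#'
#' @param tab A [cross_tabulate()] result.
#' @param lump_at Positive integer lumping threshold, in `1..k-1`.
#' @return An object of class `"diff_dist"`: a tibble with columns
#'   `difference` (labelled bin), `count` and `proportion`, carrying the
#'   lumping threshold, `k` and `n` as attributes.
#' @export
difference_distribution <- function(tab, lump_at = 3L) {
  stopifnot(inherits(tab, "cross_tab"))
  k <- tab$k
  if (lump_at < 1 || lump_at > k - 1) {
    abort(sprintf("`lump_at` must lie in 1..%d.", k - 1))
  }
  d_cell <- outer(1:k, 1:k, function(i, j) j - i)
  d_lumped <- pmin(pmax(d_cell, -lump_at), lump_at)
  bins <- seq(-lump_at, lump_at)
  cnt <- vapply(bins, function(d) sum(tab$counts[d_lumped == d]), double(1))
  labels <- as.character(bins)
  if (lump_at < k - 1) {
    labels[1] <- paste0("<=", -lump_at)
    labels[length(labels)] <- paste0(">=", lump_at)
  }
  out <- tibble(
    difference = factor(labels, levels = labels),
    count = as.integer(cnt),
    proportion = cnt / tab$n
  )
  structure(out,
    class = c("diff_dist", class(out)),
    d = bins, lump_at = as.integer(lump_at), k = k, n = tab$n
  )
}

#' Build a diff_dist directly from published lumped counts
#'
#' For reconstruction work where only the published difference table is
#' available (not the full cross-tabulation).
#'
#' @param counts Integer vector of length `2 * lump_at + 1` ordered from the
#'   "<= -lump_at" tail through 0 to the ">= lump_at" tail.
#' @param k Number of categories of the underlying indicators.
#' @param lump_at Lumping threshold used by the published table.
#' @return A `"diff_dist"` object.
#' @examples
#' # residential value index vs self-reported income, n = 676
#' as_diff_dist(c(21, 60, 129, 259, 125, 56, 26), k = 5)
#' @export
as_diff_dist <- function(counts, k, lump_at = 3L) {
  if (length(counts) != 2 * lump_at + 1) {
    abort("`counts` must have length 2 * lump_at + 1.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (lump_at > k - 1) {
    abort("`lump_at` must be at most k - 1.")
  }
  bins <- seq(-lump_at, lump_at)
  labels <- as.character(bins)
  if (lump_at < k - 1) {
    labels[1] <- paste0("<=", -lump_at)
    labels[length(labels)] <- paste0(">=", lump_at)
  }
  n <- sum(counts)
  out <- tibble(
    difference = factor(labels, levels = labels),
    count = as.integer(counts),
    proportion = counts / n
  )
  structure(out,
    class = c("diff_dist", class(out)),
    d = bins, lump_at = as.integer(lump_at), k = as.integer(k), n = n
  )
}

#' Proportion of subjects concordant within a category tolerance
#'
#' `max_abs_diff = 0` gives perfect concordance; `max_abs_diff = 1` the
#' usual "very good concordance, at most one category apart".
#'
#' @param dd A [difference_distribution()] result.
#' @param max_abs_diff Non-negative integer, strictly below the lumping
#'   threshold (otherwise the answer is not identifiable from lumped tails).
#' @return A proportion in `[0, 1]`.
#' @export
concordance_within <- function(dd, max_abs_diff = 0L) {
  stopifnot(inherits(dd, "diff_dist"))
  lump_at <- attr(dd, "lump_at")
  if (max_abs_diff < 0) abort("`max_abs_diff` must be non-negative.")
  if (max_abs_diff >= lump_at) {
    abort(paste0(
      "`max_abs_diff` >= lumping threshold: ",
      "answer not identifiable from lumped tails."
    ))
  }
  d <- attr(dd, "d")
  sum(dd$count[abs(d) <= max_abs_diff]) / attr(dd, "n")
}

#' Linear (and identity) agreement weight matrices
#'
#' Linear weights give full credit to exact agreement and credit decreasing
#' proportionally with category distance: `w[i, j] = 1 - |i - j| / (k - 1)`.
#' For five categories the off-diagonal weights are 0.75, 0.50, 0.25 and 0
#' for differences of 1 to 4 categories. Identity weights reduce the
#' weighted kappa to the overall (unweighted) kappa.
#'
#' @param k Number of categories, >= 2.
#' @return A k x k numeric weight matrix.
#' @export
linear_weights <- function(k) {
  if (k < 2) abort("`k` must be at least 2.")
  outer(1:k, 1:k, function(i, j) 1 - abs(i - j) / (k - 1))
}

#' @rdname linear_weights
#' @export
identity_weights <- function(k) {
  if (k < 2) abort("`k` must be at least 2.")
  diag(k)
}

validate_weights <- function(w, k) {
  w <- as.matrix(w)
  if (nrow(w) != k || ncol(w) != k) {
    abort(sprintf("`weights` must be a %d x %d matrix.", k, k))
  }
  if (any(!is.finite(w)) || any(w < 0 | w > 1)) {
    abort("`weights` must lie in [0, 1].")
  }
  if (any(abs(diag(w) - 1) > 1e-12)) {
    abort("`weights` must have a unit diagonal.")
  }
  if (any(abs(w - t(w)) > 1e-12)) {
    abort("`weights` must be symmetric.")
  }
  w
}

# Observed and chance-expected weighted agreement plus the
# Fleiss-Cohen-Everitt large-sample standard error of the weighted kappa.
kappa_components <- function(counts, w) {
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < 1e-12) {
    abort("chance-expected agreement is 1: kappa is undefined.")
  }
  est <- (po - pe) / (1 - pe)
  wbar_r <- as.vector(w %*% pc)   # row-wise average weight
  wbar_c <- as.vector(t(w) %*% pr)
  adj <- outer(wbar_r, wbar_c, "+")
  var_k <- (sum(p * (w - adj * (1 - est))^2) - (est - pe * (1 - est))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  list(p_obs = po, p_exp = pe, estimate = est, se = se, n = n)
}

new_agreement_result <- function(comp, method, ci_method, conf_level,
                                 ci = NULL) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (is.null(ci)) {
    ci <- if (is.na(comp$se)) c(NA_real_, NA_real_) else {
      c(comp$estimate - z * comp$se, min(comp$estimate + z * comp$se, 1))
    }
  }
  structure(
    list(
      estimate = comp$estimate, p_obs = comp$p_obs, p_exp = comp$p_exp,
      se = comp$se, conf_low = ci[1], conf_high = ci[2],
      conf_level = conf_level, method = method, ci_method = ci_method,
      n = comp$n
    ),
    class = "agreement_result"
  )
}

boot_ci <- function(counts, w, reps, conf_level, seed) {
  n <- sum(counts)
  probs <- as.vector(counts) / n
  draw_one <- function() {
    cnt <- matrix(rmultinom(1, n, probs), nrow(counts), ncol(counts))
    p <- cnt / n
    po <- sum(w * p)
    pe <- sum(w * outer(rowSums(p), colSums(p)))
    if (1 - pe < 1e-12) return(NA_real_)
    (po - pe) / (1 - pe)
  }
  stats_fun <- function() {
    vapply(seq_len(reps), function(i) draw_one(), double(1))
  }
  ks <- if (is.null(seed)) stats_fun() else withr::with_seed(seed, stats_fun())
  alpha <- 1 - conf_level
  unname(quantile(ks, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE))
}

#' Overall (unweighted) Cohen's kappa
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)` where `P_o` is the
#' observed proportion of exact agreement and `P_e` the agreement expected
#' by chance from the marginal distributions. The default confidence
#' interval uses the Fleiss-Cohen-Everitt large-sample standard error; a
#' seeded nonparametric (multinomial) bootstrap percentile interval is
#' available as an alternative.
#'
#' @param tab A [cross_tabulate()] result.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level, default 0.95.
#' @param boot_reps Bootstrap replicates (when `ci = "bootstrap"`).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `"agreement_result"`: estimate, observed and chance-expected
#'   agreement, standard error and confidence limits. See [tidy()] and
#'   [glance()] methods.
#' @export
cohen_kappa <- function(tab, ci = c("asymptotic", "bootstrap"),
                        conf_level = 0.95, boot_reps = 2000, seed = NULL) {
  stopifnot(inherits(tab, "cross_tab"))
  ci <- arg_match(ci)
  if (tab$n < 1) abort("empty table.")
  w <- identity_weights(tab$k)
  comp <- kappa_components(tab$counts, w)
  interval <- if (ci == "bootstrap") {
    boot_ci(tab$counts, w, boot_reps, conf_level, seed)
  } else NULL
  new_agreement_result(comp, "Cohen's kappa", ci, conf_level, interval)
}

#' Weighted Cohen's kappa
#'
#' Generalizes [cohen_kappa()] so partial disagreements earn partial
#' credit: `P_o(w) = sum w[i,j] p[i,j]` and
#' `P_e(w) = sum w[i,j] p[i,.] p[.,j]`. With [linear_weights()] a
#' one-category difference counts the same anywhere on the scale. With
#' [identity_weights()] the result equals the unweighted kappa exactly.
#'
#' @inheritParams cohen_kappa
#' @param weights k x k symmetric weight matrix with unit diagonal and
#'   entries in `[0, 1]`; defaults to [linear_weights()].
#' @return An `"agreement_result"`.
#' @export
weighted_kappa <- function(tab, weights = linear_weights(tab$k),
                           ci = c("asymptotic", "bootstrap"),
                           conf_level = 0.95, boot_reps = 2000, seed = NULL) {
  stopifnot(inherits(tab, "cross_tab"))
  ci <- arg_match(ci)
  if (tab$n < 1) abort("empty table.")
  w <- validate_weights(weights, tab$k)
  comp <- kappa_components(tab$counts, w)
  interval <- if (ci == "bootstrap") {
    boot_ci(tab$counts, w, boot_reps, conf_level, seed)
  } else NULL
  new_agreement_result(comp, "weighted kappa", ci, conf_level, interval)
}

#' Reconstruct a kappa point estimate from published summaries
#'
#' When only the two marginal distributions and the observed proportion of
#' exact agreement are published (not the full cross-tabulation), the
#' unweighted kappa is still identified: `P_e` follows from the marginals
#' and `kappa = (p_obs - P_e) / (1 - P_e)`. No standard error or
#' confidence interval can be reconstructed because the joint distribution
#' is not identified from marginals alone.
#'
#' @param marginal_a,marginal_b Marginal category proportions of the two
#'   indicators (each summing to 1), row and column respectively.
#' @param p_obs Published observed proportion of exact agreement.
#' @return An `"agreement_result"` with `NA` standard error and limits.
#' @examples
#' kappa_from_summaries(
#'   c(0.302, 0.241, 0.210, 0.126, 0.121),
#'   c(0.300, 0.240, 0.210, 0.130, 0.120),
#'   p_obs = 259 / 676
#' )
#' @export
kappa_from_summaries <- function(marginal_a, marginal_b, p_obs) {
  pa <- validate_marginals(marginal_a, "marginal_a")
  pb <- validate_marginals(marginal_b, "marginal_b")
  if (length(pa) != length(pb)) {
    abort("marginals must have the same number of categories.")
  }
  if (!is.numeric(p_obs) || length(p_obs) != 1 || p_obs < 0 || p_obs > 1) {
    abort("`p_obs` must be a proportion in [0, 1].")
  }
  pe <- sum(pa * pb)
  if (1 - pe < 1e-12) {
    abort("chance-expected agreement is 1: kappa is undefined.")
  }
  comp <- list(
    p_obs = p_obs, p_exp = pe,
    estimate = (p_obs - pe) / (1 - pe), se = NA_real_, n = NA_integer_
  )
  new_agreement_result(comp, "Cohen's kappa (from summaries)", "none", 0.95,
                       ci = c(NA_real_, NA_real_))
}

#' Sharp bounds on the weighted kappa from a lumped difference table
#'
#' Published discrepancy tables often lump extreme category differences
#' (e.g. "<= -3" and ">= 3"), which leaves the weighted observed agreement
#' only partially identified: mass in a lumped tail may sit at any absolute
#' difference between the lumping threshold and `k - 1`. For weight schemes
#' that depend only on `|i - j|` (linear weights do), the extremes of
#' `P_o(w)` are attained by assigning all tail mass to the smallest
#' (upper bound) or largest (lower bound) absolute difference, giving sharp
#' bounds on the weighted kappa. `P_e(w)` is fully identified by the
#' marginals.
#'
#' @param marginal_a,marginal_b Marginal category proportions (row and
#'   column indicator).
#' @param dd A `"diff_dist"`, typically [as_diff_dist()] on published
#'   counts.
#' @param weights Weight matrix depending on `|i - j|` only.
#' @return An object of class `"kappa_bounds"` with elements `lower`,
#'   `upper`, `p_exp` and `n`.
#' @examples
#' weighted_kappa_bounds(
#'   c(0.302, 0.241, 0.210, 0.126, 0.121),
#'   c(0.300, 0.240, 0.210, 0.130, 0.120),
#'   as_diff_dist(c(21, 60, 129, 259, 125, 56, 26), k = 5)
#' )
#' @export
weighted_kappa_bounds <- function(marginal_a, marginal_b, dd,
                                  weights = NULL) {
  stopifnot(inherits(dd, "diff_dist"))
  pa <- validate_marginals(marginal_a, "marginal_a")
  pb <- validate_marginals(marginal_b, "marginal_b")
  k <- attr(dd, "k")
  if (length(pa) != k || length(pb) != k) {
    abort("marginals must match the difference distribution's k.")
  }
  if (is.null(weights)) weights <- linear_weights(k)
  w <- validate_weights(weights, k)
  wd <- w[1, ]                       # weight as a function of |d| = 0..k-1
  if (any(abs(w - outer(1:k, 1:k, function(i, j) wd[abs(i - j) + 1])) >
          1e-12)) {
    abort("`weights` must depend on |i - j| only for lumped-tail bounds.")
  }

  lump_at <- attr(dd, "lump_at")
  n <- attr(dd, "n")
  d <- attr(dd, "d")
  interior <- abs(d) < lump_at
  po_interior <- sum(dd$count[interior] * wd[abs(d[interior]) + 1]) / n
  tail_mass <- sum(dd$count[!interior]) / n
  tail_w <- wd[(lump_at:(k - 1)) + 1]
  po_hi <- po_interior + tail_mass * max(tail_w)
  po_lo <- po_interior + tail_mass * min(tail_w)

  pe <- sum(w * outer(pa, pb))
  if (1 - pe < 1e-12) {
    abort("chance-expected agreement is 1: kappa is undefined.")
  }
  structure(
    list(
      lower = (po_lo - pe) / (1 - pe),
      upper = (po_hi - pe) / (1 - pe),
      p_exp = pe, n = n, lump_at = lump_at
    ),
    class = "kappa_bounds"
  )
}

#' Spearman rank correlation between two ordinal classifications
#'
#' Mid-ranks are used for ties (the dominant case for few-category data),
#' i.e. the usual Spearman coefficient as computed by [stats::cor()].
#'
#' @param data A data frame with one row per subject.
#' @param a,b Columns (tidy-select) holding the two variables. Ordinal
#'   categories by default; continuous values may be passed instead.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_ordinal <- function(data, a, b) {
  x <- pull(data, {{ a }})
  y <- pull(data, {{ b }})
  if (length(x) < 3) abort("need at least 3 subjects.")
  if (anyNA(x) || anyNA(y)) abort("inputs must be non-missing.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("correlation undefined for a constant variable.")
  }
  cor(x, y, method = "spearman")
}
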