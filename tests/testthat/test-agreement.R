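test_that("cross-tabulation counts pairs and preserves marginals", {
  d <- tibble::tibble(a = c(1L, 2L), b = c(1L, 2L))
  tab <- cross_tabulate(d, a, b, k = 2)
  expect_equal(tab$counts, diag(c(1L, 1L)))
  anti <- cross_tabulate(tibble::tibble(a = 1:2, b = 2:1), a, b, k = 2)
  expect_equal(diag(anti$counts), c(0L, 0L))

  set.seed(10)
  d <- tibble::tibble(
    a = sample(1:5, 100, replace = TRUE),
    b = sample(1:5, 100, replace = TRUE)
  )
  tab <- cross_tabulate(d, a, b, k = 5)
  expect_equal(rowSums(tab$counts),
               unname(as.vector(table(factor(d$a, levels = 1:5)))))
  expect_equal(colSums(tab$counts),
               unname(as.vector(table(factor(d$b, levels = 1:5)))))
  expect_equal(tab$n, 100L)

  expect_error(cross_tabulate(d[0, ], a, b), "zero subjects")
  expect_error(cross_tabulate(tibble::tibble(a = 0L, b = 1L), a, b, k = 2),
               "positive integers")
  expect_error(cross_tabulate(tibble::tibble(a = 3L, b = 1L), a, b, k = 2),
               "out of range")
})

test_that("difference distribution matches an exhaustive cell tally", {
  diag_tab <- as_cross_tab(diag(c(5L, 3L, 2L, 1L, 4L)))
  dd <- difference_distribution(diag_tab)
  expect_equal(dd$count[attr(dd, "d") == 0], 15L)
  expect_equal(sum(dd$count), 15L)

  one_far <- matrix(0L, 5, 5); one_far[1, 5] <- 1L; one_far[1, 1] <- 3L
  dd <- difference_distribution(as_cross_tab(one_far), lump_at = 3)
  expect_equal(dd$count[attr(dd, "d") == 3], 1L)  # d = 4 lumps into >= 3

  set.seed(11)
  m <- random_table(5)
  dd <- difference_distribution(as_cross_tab(m), lump_at = 3)
  tally <- setNames(rep(0, 7), -3:3)
  for (i in 1:5) for (j in 1:5) {
    d <- min(max(j - i, -3), 3)
    tally[as.character(d)] <- tally[as.character(d)] + m[i, j]
  }
  expect_equal(dd$count, as.integer(unname(tally)))
  expect_error(difference_distribution(as_cross_tab(m), lump_at = 5),
               "lump_at")
})

test_that("concordance proportions recover the published figures", {
  inp <- montreal_inputs()
  dd_res <- as_diff_dist(inp$d_residential, k = 5)
  dd_cen <- as_diff_dist(inp$d_census, k = 5)
  expect_equal(concordance_within(dd_res, 0), 259 / 676)
  expect_equal(concordance_within(dd_cen, 1), (139 + 200 + 129) / 676)
  expect_error(concordance_within(dd_res, 3), "not identifiable")

  all_diag <- difference_distribution(as_cross_tab(diag(rep(2L, 5))), 3)
  expect_equal(concordance_within(all_diag, 0), 1)
})

test_that("linear weights step down by 1/(k-1) per category difference", {
  w5 <- linear_weights(5)
  expect_equal(w5[1, 1:5], c(1, 0.75, 0.50, 0.25, 0))
  expect_equal(w5, t(w5))
  expect_equal(diag(w5), rep(1, 5))
  expect_equal(linear_weights(2), diag(2))
  expect_error(linear_weights(1), "at least 2")
})

test_that("kappa hits the classical anchor points", {
  ident <- as_cross_tab(diag(rep(10L, 4)))
  expect_equal(cohen_kappa(ident)$estimate, 1)
  expect_equal(weighted_kappa(ident)$estimate, 1)

  indep <- as_cross_tab(matrix(25L, 2, 2))
  expect_equal(cohen_kappa(indep)$estimate, 0)

  both_degenerate <- matrix(c(5L, 0L, 0L, 0L), 2, 2)
  expect_error(cohen_kappa(as_cross_tab(both_degenerate)), "undefined")
})

test_that("kappa and its standard error match an independent implementation", {
  # reference values computed once with statsmodels cohens_kappa
  tab <- as_cross_tab(matrix(
    c(30, 10, 5, 2, 8, 25, 9, 4, 3, 11, 28, 7, 1, 5, 9, 20),
    4, 4, byrow = TRUE
  ))
  k0 <- cohen_kappa(tab)
  expect_equal(k0$estimate, 0.439177906230, tolerance = 1e-9)
  expect_equal(k0$se, 0.049928146908, tolerance = 1e-9)
  expect_equal(k0$conf_low, k0$estimate - stats::qnorm(0.975) * k0$se,
               tolerance = 1e-9)
  kw <- weighted_kappa(tab, linear_weights(4))
  expect_equal(kw$estimate, 0.537908760597, tolerance = 1e-9)
  expect_equal(kw$se, 0.048364878251, tolerance = 1e-9)
})

test_that("weighted kappa agrees with the double-loop oracle on random tables", {
  set.seed(12)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    m <- random_table(k)
    w <- linear_weights(k)
    got <- weighted_kappa(as_cross_tab(m), w)
    want <- oracle_kappa(m, w)
    expect_equal(got$estimate, want$estimate)
    expect_equal(got$p_obs, want$p_obs)
    expect_equal(got$p_exp, want$p_exp)
  }
})

test_that("identity-weight reduction and label-reversal symmetry hold", {
  set.seed(13)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    m <- random_table(k)
    tab <- as_cross_tab(m)
    expect_equal(weighted_kappa(tab, identity_weights(k))$estimate,
                 cohen_kappa(tab)$estimate, tolerance = 1e-12)
    rev_tab <- as_cross_tab(m[k:1, k:1])
    expect_equal(cohen_kappa(rev_tab)$estimate, cohen_kappa(tab)$estimate,
                 tolerance = 1e-12)
    expect_equal(weighted_kappa(rev_tab, linear_weights(k))$estimate,
                 weighted_kappa(tab, linear_weights(k))$estimate,
                 tolerance = 1e-12)
  }
})

test_that("agreement results satisfy their defining identity", {
  set.seed(14)
  for (i in 1:20) {
    tab <- as_cross_tab(random_table(4))
    r <- weighted_kappa(tab, linear_weights(4))
    expect_equal(r$estimate, (r$p_obs - r$p_exp) / (1 - r$p_exp),
                 tolerance = 1e-12)
    expect_lte(r$estimate, 1)
    expect_true(r$conf_low <= r$estimate && r$estimate <= r$conf_high)
  }
})

test_that("bootstrap intervals are seeded and contain the estimate", {
  tab <- as_cross_tab(matrix(
    c(30, 10, 5, 2, 8, 25, 9, 4, 3, 11, 28, 7, 1, 5, 9, 20),
    4, 4, byrow = TRUE
  ))
  b1 <- weighted_kappa(tab, ci = "bootstrap", boot_reps = 500, seed = 9)
  b2 <- weighted_kappa(tab, ci = "bootstrap", boot_reps = 500, seed = 9)
  expect_equal(b1$conf_low, b2$conf_low)
  expect_equal(b1$conf_high, b2$conf_high)
  expect_true(b1$conf_low < b1$estimate && b1$estimate < b1$conf_high)
  # point estimate does not depend on the CI method
  expect_equal(b1$estimate, weighted_kappa(tab)$estimate)
})

test_that("kappa is reconstructible from published marginal summaries", {
  inp <- montreal_inputs()
  r1 <- kappa_from_summaries(inp$self, inp$residential, 259 / 676)
  expect_equal(round(r1$estimate, 2), 0.21)
  r2 <- kappa_from_summaries(inp$self, inp$census, 200 / 676)
  expect_equal(round(r2$estimate, 2), 0.09)
  expect_true(is.na(r1$se) && is.na(r1$conf_low))

  p <- c(0.3, 0.3, 0.4)
  pe <- sum(p * p)
  expect_equal(kappa_from_summaries(p, p, pe)$estimate, 0)
})

test_that("lumped-tail bounds are sharp and contain the exact value", {
  inp <- montreal_inputs()
  # empty tails: bounds collapse to the exact weighted kappa
  m <- matrix(0L, 5, 5)
  m[cbind(1:5, 1:5)] <- 8L; m[1, 3] <- 4L; m[4, 2] <- 3L
  tab <- as_cross_tab(m)
  p_r <- rowSums(m) / sum(m); p_c <- colSums(m) / sum(m)
  dd <- difference_distribution(tab, lump_at = 3)
  b <- weighted_kappa_bounds(p_r, p_c, dd)
  exact <- weighted_kappa(tab, linear_weights(5))$estimate
  expect_equal(b$lower, exact, tolerance = 1e-12)
  expect_equal(b$upper, exact, tolerance = 1e-12)

  # exact kappa always lies inside bounds from its own lumped summary
  set.seed(15)
  for (i in 1:40) {
    m <- random_table(5)
    tab <- as_cross_tab(m)
    dd <- difference_distribution(tab, lump_at = sample(2:3, 1))
    b <- weighted_kappa_bounds(rowSums(m) / sum(m), colSums(m) / sum(m), dd)
    exact <- weighted_kappa(tab, linear_weights(5))$estimate
    expect_lte(b$lower, exact + 1e-12)
    expect_gte(b$upper + 1e-12, exact)
    expect_lte(b$lower, b$upper)
  }

  asym <- matrix(0.5, 3, 3); diag(asym) <- 1; asym[1, 3] <- 0.2
  asym[3, 1] <- 0.2; asym[1, 2] <- 0.7; asym[2, 1] <- 0.7
  expect_error(
    weighted_kappa_bounds(inp$self[1:3] / sum(inp$self[1:3]),
                          inp$self[1:3] / sum(inp$self[1:3]),
                          as_diff_dist(c(1, 2, 3, 2, 1), k = 3, lump_at = 2),
                          asym),
    "\\|i - j\\|"
  )
})

test_that("spearman uses mid-ranks and matches a rank-then-pearson oracle", {
  d <- tibble::tibble(a = 1:10, b = 1:10)
  expect_equal(spearman_ordinal(d, a, b), 1)
  expect_equal(spearman_ordinal(tibble::tibble(a = 1:10, b = 10:1), a, b), -1)

  set.seed(16)
  d <- tibble::tibble(
    a = sample(1:5, 60, replace = TRUE),
    b = sample(1:5, 60, replace = TRUE)
  )
  expect_equal(
    spearman_ordinal(d, a, b),
    stats::cor(rank(d$a), rank(d$b), method = "pearson")
  )
  expect_error(
    spearman_ordinal(tibble::tibble(a = rep(1, 5), b = 1:5), a, b),
    "constant"
  )
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  tab <- as_cross_tab(diag(rep(5L, 3)) + 1L)
  r <- weighted_kappa(tab, linear_weights(3))
  td <- tidy(r)
  expect_named(td, c("method", "estimate", "std.error", "conf.low",
                     "conf.high"))
  expect_equal(nrow(td), 1)
  gl <- glance(r)
  expect_equal(gl$n, tab$n)

  inp <- montreal_inputs()
  b <- weighted_kappa_bounds(inp$self, inp$residential,
                             as_diff_dist(inp$d_residential, k = 5))
  expect_named(tidy(b), c("lower", "upper", "p_exp", "n"))
})
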