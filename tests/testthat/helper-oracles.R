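# Naive double-loop oracle for (weighted) kappa: every sum written out as
# explicit loops, independent of the package's matrix-algebra path.
oracle_kappa <- function(counts, w) {
  k <- nrow(counts)
  n <- 0
  for (i in 1:k) for (j in 1:k) n <- n + counts[i, j]
  po <- 0
  for (i in 1:k) for (j in 1:k) po <- po + w[i, j] * counts[i, j] / n
  pe <- 0
  for (i in 1:k) {
    row_i <- 0
    for (j in 1:k) row_i <- row_i + counts[i, j] / n
    for (j in 1:k) {
      col_j <- 0
      for (i2 in 1:k) col_j <- col_j + counts[i2, j] / n
      pe <- pe + w[i, j] * row_i * col_j
    }
  }
  list(p_obs = po, p_exp = pe, estimate = (po - pe) / (1 - pe))
}

# Random k x k count table; guarantees a non-degenerate chance agreement.
random_table <- function(k, max_count = 20) {
  repeat {
    m <- matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
    if (sum(m) == 0) next
    p <- m / sum(m)
    if (sum(rowSums(p) * colSums(p)) < 1 - 1e-9) {
      return(m)
    }
  }
}

# Published summary inputs used across reconstruction tests.
montreal_inputs <- function() {
  tabs <- montreal_income_tables()
  m <- tabs$marginals
  list(
    self = m$pct_total[m$indicator == "self_report"] / 100,
    residential = m$pct_total[m$indicator == "residential"] / 100,
    census = m$pct_total[m$indicator == "census"] / 100,
    d_residential = tabs$differences$count[
      tabs$differences$comparison == "residential"
    ],
    d_census = tabs$differences$count[
      tabs$differences$comparison == "census"
    ],
    n = tabs$n
  )
}

# Tiny deterministic cohort used as a shared fixture.
tiny_cohort <- function() {
  generate_cohort(cohort_config(n_subjects = 12, seed = 101))
}
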