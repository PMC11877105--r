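test_that("normality gate routes Gaussian data parametric, skewed data not", {
  set.seed(31)
  a <- rnorm(25); b <- rnorm(25, 1)
  expect_equal(normality_gate(a, b), "parametric")

  skew <- rlnorm(25, sdlog = 1.5)
  expect_equal(normality_gate(a, skew), "nonparametric")

  expect_warning(g <- normality_gate(c(1, 2), b), "too small")
  expect_equal(g, "nonparametric")
})

test_that("continuous comparison dispatches and formats per the chosen path", {
  set.seed(30)
  a <- rnorm(20, 5); b <- rnorm(20, 6)
  r <- compare_continuous(a, b, variable = "v")
  expect_equal(r$test_used, "student_t")
  expect_match(r$summary_a, "^[-0-9.]+ \\([-0-9.]+\\)$")  # mean (SD)
  expect_equal(r$n_a, 20)

  # swapping groups flips the statistic's sign, not the p-value
  r2 <- compare_continuous(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)

  skew <- rlnorm(20, sdlog = 1.5)
  r3 <- compare_continuous(a, skew)
  expect_equal(r3$test_used, "mann_whitney")
  expect_match(r3$summary_b, "-")  # median (q1-q3)

  # identical constant groups: no difference, p = 1 by convention
  expect_message(r4 <- compare_continuous(rep(2, 5), rep(2, 5)),
                 "identical")
  expect_equal(r4$p_value, 1)
  expect_equal(r4$statistic, 0)

  # Welch flavour on request
  r5 <- compare_continuous(a, b, var_equal = FALSE)
  expect_equal(r5$test_used, "welch_t")
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(33)
  a <- rlnorm(15); b <- rlnorm(12, 0.8)
  p0 <- suppressWarnings(wilcox.test(a, b))$p.value
  for (f in list(log, sqrt, function(x) x^3, function(x) exp(x / 10))) {
    r <- compare_continuous(f(a), f(b))
    if (r$test_used == "mann_whitney")
      expect_equal(r$p_value, p0, tolerance = 1e-10)
  }
})

test_that("Fisher two-sided p matches brute-force enumeration and anchors", {
  # observed comorbidity rows: 0/32 vs 4/25 and 6/32 vs 0/25
  expect_equal(round(fisher_exact_2x2(0, 32, 4, 21), 3), 0.032)
  expect_equal(round(fisher_exact_2x2(6, 26, 0, 25), 3), 0.030)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 10, 0, 12), 1)  # zero margin

  set.seed(34)
  for (i in 1:100) {
    cells <- rpois(4, sample(c(2, 5, 10), 1))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 brute_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("sample-size calculator reproduces the study's 10 per arm", {
  s <- sample_size_two_means(0.30, 0.13, 0.62, alpha = 0.05, power = 0.90)
  expect_equal(s$n_per_arm, 10L)
  expect_equal(s$n_unrounded, 10.27, tolerance = 1e-2)

  # numeric oracle: solve power(n) = target on the normal approximation
  pow <- function(n, delta, sd, alpha) {
    se <- sd * sqrt(2 / n)
    pnorm(delta / se - qnorm(1 - alpha / 2))
  }
  n_oracle <- uniroot(function(n) pow(n, 0.30 * 0.62, 0.13, 0.05) - 0.90,
                      c(1, 1e4))$root
  expect_equal(s$n_unrounded, n_oracle, tolerance = 1e-6)

  # monotonicity: doubling sd at fixed delta quadruples n; lower power
  # needs fewer subjects; ceiling rounds up
  expect_equal(sample_size_two_means(0.30, 0.26, 0.62)$n_unrounded,
               4 * s$n_unrounded)
  expect_lt(sample_size_two_means(0.30, 0.13, 0.62, power = 0.80)$n_unrounded,
            s$n_unrounded)
  expect_equal(sample_size_two_means(0.30, 0.13, 0.62,
                                     rounding = "ceiling")$n_per_arm, 11L)
  expect_error(sample_size_two_means(0, 0.13, 0.5), "zero")
})

test_that("viability quadrants partition events and recover known fractions", {
  q <- viability_quadrants(anv = c(FALSE, FALSE), pi = c(FALSE, FALSE))
  expect_equal(q$viable, 1)
  expect_equal(q$early_apoptotic + q$late_apoptotic + q$necrotic, 0)

  q2 <- viability_quadrants(anv = c(TRUE, TRUE), pi = c(FALSE, TRUE))
  expect_equal(q2$early_apoptotic, 0.5)
  expect_equal(q2$late_apoptotic, 0.5)

  probs <- c(0.6, 0.2, 0.15, 0.05)
  ev <- simulate_viability_events(10000, probs, seed = 35)
  q3 <- viability_quadrants(ev$anv, ev$pi)
  got <- c(q3$viable, q3$early_apoptotic, q3$late_apoptotic, q3$necrotic)
  expect_equal(sum(got), 1)
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(got - probs) < 3 * se))
})

test_that("isotype-gated marker summary recovers a known positive fraction", {
  sim <- simulate_marker_events(5000, pos_fraction = 0.68, seed = 36)
  ms <- marker_summary(sim$events, sim$isotype_events, marker = "CD10")
  se <- 100 * sqrt(0.68 * 0.32 / 5000)
  expect_lt(abs(ms$percent_positive - 68), 3 * se + 1)  # +1%: gate spillover
  expect_true(ms$percent_positive >= 0 && ms$percent_positive <= 100)
  expect_equal(marker_summary(rep(7, 50), rep(7, 50))$mfi, 7)
  expect_equal(marker_summary(c(1, 2, 3), c(10, 11, 12))$percent_positive, 0)
  expect_error(marker_summary(1:5, NULL), "isotype")

  # double-positive maturity fraction
  sim2 <- simulate_marker_events(5000, pos_fraction = 0.9, seed = 37)
  mat <- maturity_fraction(sim$events, sim2$events,
                           sim$isotype_events, sim2$isotype_events)
  expect_lt(abs(mat - 100 * mean(sim$is_positive & sim2$is_positive)), 3)
})

test_that("comparison table dispatches by type and reports exceptions", {
  cohort <- simulate_cohort(
    c(control = 20, CAP = 18),
    list(
      ci = list(type = "normal", mean = c(control = 0.31, CAP = 0.14),
                sd = c(control = 0.13, CAP = 0.03)),
      dementia = list(type = "categorical",
                      prob = list(control = c(no = 1, yes = 0),
                                  CAP = c(no = 0.84, yes = 0.16)))),
    seed = 41)
  cohort$all_missing <- ifelse(cohort$group == "CAP", NA, 1.0)
  ct <- run_comparison_table(cohort,
                             variables = c("ci", "dementia", "all_missing",
                                           "not_a_column"))
  expect_equal(nrow(ct$results), 2)
  expect_setequal(ct$results$test_used, c("student_t", "fisher_exact"))
  expect_setequal(ct$exceptions$variable, c("all_missing", "not_a_column"))
  expect_match(ct$exceptions$reason[ct$exceptions$variable == "not_a_column"],
               "unknown")

  # zero-probability category gives zero counts in that arm every seed
  expect_equal(sum(cohort$dementia[cohort$group == "control"] == "yes"), 0)

  # BH adjustment is the step-up procedure: monotone after sorting raw p
  cohort2 <- simulate_cohort(
    c(control = 15, CAP = 15),
    setNames(lapply(1:6, function(i)
      list(type = "normal", mean = c(control = 0, CAP = i / 10),
           sd = c(control = 1, CAP = 1))), paste0("v", 1:6)),
    seed = 39)
  ct2 <- run_comparison_table(cohort2, adjust = "BH")
  o <- order(ct2$results$p_value)
  expect_true(all(diff(ct2$results$p_adjusted[o]) >= -1e-12))
  expect_true(all(ct2$results$p_adjusted >= ct2$results$p_value))
})
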