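test_that("Welch test matches its closed form and handles identity", {
  set.seed(41)
  a <- rnorm(12, 10, 2); b <- rnorm(17, 11, 3)
  w <- welch_test(a, b)
  ref <- naive_welch(a, b)
  expect_equal(abs(w$t), abs(ref$t), tolerance = 1e-12)
  expect_equal(w$df, ref$df, tolerance = 1e-9)
  expect_equal(w$p, ref$p, tolerance = 1e-12)
  same <- c(1, 2, 3, 4)
  w0 <- welch_test(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
})

test_that("Holm adjustment matches the longhand computation", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03))$adjusted,
               c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2)$adjusted, 0.2)
  set.seed(42)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- holm_bonferroni(p)$adjusted
    expect_equal(adj, naive_holm(p))
    expect_true(all(adj >= p))
    # idempotent on already-adjusted values
    expect_equal(holm_bonferroni(adj)$adjusted >= adj, rep(TRUE, length(p)))
  }
})

test_that("TOST p-value and confidence-interval rules always agree", {
  set.seed(43)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1), 100, 10)
    b <- rnorm(sample(5:40, 1), 100 * (1 + runif(1, -0.6, 0.6)), 12)
    eq <- tost_equivalence(a, b)
    ci_rule <- eq$ci[1] > eq$delta_lower && eq$ci[2] < eq$delta_upper
    expect_identical(eq$equivalent, ci_rule)
  }
})

test_that("TOST verdicts behave at the obvious extremes", {
  set.seed(44)
  big_a <- rnorm(5000, 100, 10)
  big_b <- rnorm(5000, 100, 10)
  expect_true(tost_equivalence(big_a, big_b)$equivalent)
  far <- rnorm(5000, 200, 10)
  expect_false(tost_equivalence(big_a, far)$equivalent)
  expect_error(tost_equivalence(1, c(1, 2)), "at least two")
  expect_error(tost_equivalence(c(-1, 1), c(0, 1)),
               "control mean is zero")
  # a CI of (-1, 1) against bounds of +/-2 is equivalent by definition
  eq <- tost_equivalence(rnorm(50, 10, 0.5), rnorm(50, 10, 0.5), bounds = 2)
  expect_true(eq$ci[1] > -2 && eq$ci[2] < 2)
  expect_true(eq$equivalent)
})

test_that("TOST power grows with sample size at zero effect", {
  power_at <- function(n) {
    mean(vapply(1:200, function(i) {
      g <- gen_group_samples(group_sim_spec(n_per_group = n,
                                            relative_effect = 0,
                                            coefficient_of_variation = 0.35,
                                            seed = 5000 + i))
      tost_equivalence(g$control, g$treated)$equivalent
    }, logical(1)))
  }
  expect_lt(power_at(5), power_at(40))
})

test_that("replicate summaries and correlations are exact", {
  expect_equal(summarize_replicates(1:5), 3)
  expect_equal(summarize_replicates(42), 42)
  set.seed(45)
  v <- runif(7)
  expect_equal(summarize_replicates(v), sum(v) / 7)
  x <- rnorm(30)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  # bivariate simulation recovers the population correlation
  rho <- -0.6
  z <- rnorm(5000)
  y <- rho * z + sqrt(1 - rho^2) * rnorm(5000)
  est <- correlate(z, y)
  expect_equal(est$r, rho, tolerance = 0.05)
  expect_lt(est$p, 0.01)
})

test_that("troponin release bound reproduces the worked example", {
  est <- troponin_release_bound(0.045, 0.040, 0.35)
  expect_identical(est$released_upper_bound, 0.045 * 0.040)
  expect_equal(est$released_upper_bound, 0.0018)
  expect_equal(est$damage_fraction_upper_bound, 0.0018 / 0.35)
  expect_equal(troponin_release_bound(0, 0.040)$released_upper_bound, 0)
  expect_error(troponin_release_bound(0.045, -1), "positive")
  expect_error(troponin_release_bound(0.045, 0.04, 0), "positive")
})

test_that("group simulation hits its population targets", {
  g0 <- gen_group_samples(group_sim_spec(relative_effect = 0, seed = 7))
  expect_equal(length(g0$control), 20)
  expect_identical(g0$truth$control_mean, g0$truth$treated_mean)
  g3 <- gen_group_samples(group_sim_spec(relative_effect = 0.3, seed = 7))
  expect_equal(g3$truth$treated_mean, 1.3 * g3$truth$control_mean)
  # sample means converge to the truth as n grows
  big <- gen_group_samples(group_sim_spec(n_per_group = 20000,
                                          relative_effect = 0.3, seed = 8))
  expect_equal(mean(big$control), 100, tolerance = 0.5)
  expect_equal(mean(big$treated), 130, tolerance = 0.5)
})

test_that("equivalence tables run Welch, Holm and TOST per metric", {
  set.seed(46)
  df <- rbind(
    data.frame(group = "CTRL", metric = "m1", value = rnorm(15, 10, 1)),
    data.frame(group = "CS", metric = "m1", value = rnorm(15, 10, 1)),
    data.frame(group = "CSP", metric = "m1", value = rnorm(15, 18, 1)),
    data.frame(group = "CTRL", metric = "m2", value = rnorm(15, 5, 0.2)),
    data.frame(group = "CS", metric = "m2", value = rnorm(15, 5, 0.2)),
    data.frame(group = "CSP", metric = "m2", value = rnorm(15, 5, 0.2)))
  tab <- equivalence_table(df, control = "CTRL")
  expect_equal(nrow(tab), 4L)
  expect_true(tab$equivalent[tab$metric == "m1" & tab$group == "CS"])
  expect_false(tab$equivalent[tab$metric == "m1" & tab$group == "CSP"])
  expect_true(all(tab$welch_p_holm >= tab$welch_p))
})
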