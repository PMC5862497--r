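test_that("Wilson intervals match the prop.test score oracle", {
  cases <- list(c(62, 350), c(0, 31), c(15, 50), c(27, 31), c(1, 1416))
  for (cs in cases) {
    est <- wilson_ci(cs[1], cs[2])
    oracle <- prop.test(cs[1], cs[2], correct = FALSE)$conf.int
    expect_equal(c(est$lower, est$upper), as.numeric(oracle),
                 tolerance = 1e-9)
    expect_gte(est$point, est$lower)
    expect_lte(est$point, est$upper)
  }
  expect_gt(wilson_ci(0, 31)$upper, 0)   # 0/n still has mass above zero
  cp <- wilson_ci(3, 10, method = "clopper-pearson")
  expect_equal(c(cp$lower, cp$upper),
               as.numeric(binom.test(3, 10)$conf.int))
  expect_error(wilson_ci(1, 0), "zero trials")
})

test_that("estimate_rates works from counts and from event logs", {
  est <- estimate_rates(initial_count = 62, n_divisions = 350,
                        transmitted_count = 46, n_initial = 62)
  expect_equal(est$i$point, 62 / 350)
  expect_equal(round(est$i$point, 3), 0.177)
  expect_equal(est$t$point, 46 / 62)
  sim <- run_simulation(sim_config("recB", n_initial = 200,
                                   n_generations = 8, seed = 3,
                                   record = "all"))
  est2 <- estimate_rates(sim$events)
  expect_equal(est2$i$n, nrow(sim$events))
  expect_error(estimate_rates(initial_count = 0, n_divisions = 0),
               "zero divisions")
})

test_that("h and per-fork rates are exact arithmetic", {
  expect_equal(heritable_division_fraction(0.177, 0.75), 0.13275)
  expect_equal(heritable_division_fraction(0.07, 0.37), 0.0259)
  expect_equal(heritable_division_fraction(0.2, 0), 0)
  expect_lte(heritable_division_fraction(0.3, 0.8), 0.3)  # h <= i
  expect_equal(per_fork_rate(0.18), 0.09)
  expect_equal(per_fork_rate(0), 0)
  expect_equal(per_fork_rate(0.18, "independent-forks"),
               1 - sqrt(1 - 0.18))
  # oracle: the independent-forks value solves 1-(1-x)^2 = p
  x <- per_fork_rate(0.18, "independent-forks")
  expect_equal(1 - (1 - x)^2, 0.18, tolerance = 1e-12)
  expect_lte(per_fork_rate(0.5), 0.5)
})

test_that("steady_state_fraction collapses and matches the recursion oracle", {
  # t = 0, non-dividing focus-less: fraction equals the initial fraction
  expect_equal(as.numeric(steady_state_fraction(0.12, 0)), 0.12,
               tolerance = 1e-10)
  # recB inputs vs the iterated recursion d' = (d+q)/(2-q)
  s <- steady_state_fraction(0.177, 0.745)
  q <- attr(s, "details")$q
  expect_equal(as.numeric(s), recursion_fraction(q), tolerance = 1e-9)
  # infeasible observed pair is rejected, not silently truncated
  expect_error(steady_state_fraction(0.25, 0.9), "infeasible")
  expect_error(steady_state_fraction(0.1, 0.5,
                                     first_division_dist = c(0.5, 0.4)),
               "probability vectors")
})

test_that("degradation-scale fitting: closed form, flags, ordering", {
  fit <- fit_degradation_scale(c(10, 300), c(0.32, 0.079))
  expect_equal(fit$scale_kb, 290 / log(32 / 7.9), tolerance = 1e-9)
  expect_true(fit$identifiable)
  flat <- fit_degradation_scale(c(10, 300), c(0.2, 0.2))
  expect_false(flat$identifiable)
  expect_equal(flat$scale_kb, Inf)
  fit3 <- fit_degradation_scale(c(10, 300, 500), c(0.273, 0.23, 0.11))
  expect_gt(fit3$scale_kb, fit$scale_kb)
  expect_error(fit_degradation_scale(10, 0.3), "two points")
  expect_error(fit_degradation_scale(c(10, 10), c(0.3, 0.2)), "distinct")
  expect_error(fit_degradation_scale(c(10, 300), c(0, 0.2)), "fractions")
})

test_that("degradation-scale fit recovers generating scales on synthetic data", {
  set.seed(8)
  true_scale <- 207; q <- 0.3; n <- 2e4
  d <- c(10, 100, 300, 500)
  f <- rbinom(length(d), n, q * exp(-d / true_scale)) / n
  fit <- fit_degradation_scale(d, f)
  expect_lt(abs(fit$scale_kb - true_scale) / true_scale, 0.10)
  # and a larger scale
  f2 <- rbinom(length(d), n, q * exp(-d / 600)) / n
  fit2 <- fit_degradation_scale(d, f2)
  expect_lt(abs(fit2$scale_kb - 600) / 600, 0.10)
})

test_that("consistency report accepts recB and recA within tolerance", {
  rep <- consistency_report(c("recB", "recA"), n_initial = 800,
                            n_generations = 20, population_cap = 2e4,
                            seed = 2)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$closed_form_ok))
  expect_true(all(rep$simulated_ok))
  expect_equal(rep$h[rep$genotype == "recB"], 0.177 * 0.745)
})
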