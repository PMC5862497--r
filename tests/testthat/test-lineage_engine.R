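test_that("no breakage means exact doubling with NORMAL events only", {
  p <- test_params(0, 0)
  pop <- new_population(40)
  set.seed(1)
  st <- step_generation(pop, p, map_circ, generation = 1)
  expect_equal(nrow(st$population), 80)
  expect_true(all(st$events$classification == "NORMAL"))
  expect_equal(st$counts$n_divisions, 40)
})

test_that("simulations are deterministic given the seed", {
  cfg <- sim_config("recB", n_initial = 60, n_generations = 6, seed = 99,
                    record = "all")
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$final_population, s2$final_population)
  expect_identical(s1$events, s2$events)
  s3 <- run_simulation(sim_config("recB", n_initial = 60,
                                  n_generations = 6, seed = 100,
                                  record = "all"))
  expect_false(identical(s1$final_population, s3$final_population))
})

test_that("zero generations and wild-type degenerate cases", {
  s0 <- run_simulation(sim_config("recB", n_initial = 25,
                                  n_generations = 0, seed = 1))
  expect_equal(nrow(s0$final_population), 25)
  expect_equal(nrow(s0$events), 0)
  wt <- run_simulation(sim_config("wild_type", n_initial = 50,
                                  n_generations = 8, seed = 5))
  for (loc in names(map_circ$loci))
    expect_true(all(locus_present(wt$final_population, map_circ, loc)))
  expect_equal(sum(wt$per_generation$n_initial), 0)
})

test_that("config validation names the offending fields", {
  expect_error(sim_config("recB", n_initial = 0, seed = 1), "n_initial")
  expect_error(sim_config("recB", seed = NA), "seed")
  expect_error(run_simulation(structure(list(), class = "list")))
})

test_that("cleavage position honours genotype and topology", {
  expect_equal(cleavage_position(default_params("recB"), map_circ, 3),
               rep(1588, 3))
  expect_equal(cleavage_position(default_params("recB"), map_lin, 2),
               rep(1585, 2))
  set.seed(2)
  x <- cleavage_position(default_params("matP_ftsK_dCter_recB"),
                         map_circ, 200)
  expect_true(all(in_fork_trap(map_circ, x)))
  expect_gt(diff(range(x)), 100)  # genuinely spread over the trap
})

test_that("degradation is monotone and inactive at scale zero", {
  cells <- new_population(5)
  cells$lost_a <- rep(1588, 5); cells$lost_b <- rep(1588, 5)
  p0 <- test_params(0.1, 0, scale = 0)
  expect_equal(degrade_ends(cells, p0, map_circ), cells)
  p <- test_params(0.1, 0, scale = 150)
  set.seed(3)
  for (rep in 1:10) {
    len_before <- (cells$lost_b - cells$lost_a) %% map_circ$length_kb
    cells <- degrade_ends(cells, p, map_circ)
    len_after <- (cells$lost_b - cells$lost_a) %% map_circ$length_kb
    expect_true(all(len_after >= len_before - 1e-9))
    expect_true(all(len_after < map_circ$length_kb))
  }
})

test_that("event log classifications respect the carrier contract", {
  sim <- run_simulation(sim_config("recB", n_initial = 150,
                                   n_generations = 10, seed = 7,
                                   record = "all"))
  ev <- sim$events
  expect_true(all(ev$classification %in%
                    c("NORMAL", "INITIAL", "TRANSMITTED")))
  # every TRANSMITTED event continues a chain opened by an INITIAL event
  init_chains <- ev$chain[ev$classification == "INITIAL"]
  trans_chains <- ev$chain[ev$classification == "TRANSMITTED"]
  expect_true(all(trans_chains %in% init_chains))
  expect_true(all(is.na(ev$chain[ev$classification == "NORMAL"])))
  # first-vs-later asymmetry on the population
  pop <- sim$final_population
  expect_true(all(pop$state[!is.na(pop$lost_a)] %in%
                    c("TRUNCATED_LINEAR", "FULL_LINEAR_WITH_ENDS")))
  # cell-count conservation: each division adds exactly one cell
  pg <- sim$per_generation
  expect_equal(nrow(pop),
               150 + sum(pg$n_divisions) + sum(pg$n_focusless_divisions))
})

test_that("recB time-lapse statistics reproduce the calibrated rates", {
  sim <- run_quick("recB", n_initial = 1500, n_generations = 18,
                   cap = 4e4, seed = 11)
  ts <- timelapse_stats(sim, burn_in = 6)
  expect_gt(ts$n_divisions, 1e5)
  expect_lt(abs(ts$initial_fraction - 0.177), 0.01)
  expect_lt(abs(ts$transmitted_fraction - 0.745), 0.02)
})

test_that("engine matches the closed-form implied rates", {
  p <- test_params(0.22, 0.6)
  cfg <- sim_config(p, n_initial = 1200, n_generations = 16,
                    population_cap = 3e4, seed = 13, record = "none")
  sim <- run_simulation(cfg)
  ts <- timelapse_stats(sim, burn_in = 6)
  th <- implied_event_rates(p)
  expect_lt(abs(ts$initial_fraction - th$initial_fraction), 0.012)
  pop <- sim$final_population
  carrier_frac <- mean(pop$carrier[pop$viable])
  expect_lt(abs(carrier_frac - th$carrier_fraction), 0.015)
})

test_that("linear topology: no carriers, hipAB-side daughters inert", {
  sim <- run_simulation(sim_config("recB", topology = "linear",
                                   n_initial = 400, n_generations = 12,
                                   population_cap = 2e4, seed = 17,
                                   record = "events"))
  pop <- sim$final_population
  expect_false(any(pop$carrier))
  expect_equal(sum(sim$per_generation$n_transmitted), 0)
  # daughters that lost hipAB never divide
  fl <- pop[!is.na(pop$lost_a), ]
  hip_lost <- !locus_present(fl, map_lin, "ydeV") &
    mapply(function(a, b) {
      x <- map_lin$hip_pos
      if (a <= b) x >= a && x <= b else x >= a || x <= b
    }, fl$lost_a, fl$lost_b)
  expect_true(all(fl$div_rem[hip_lost] == 0))
  expect_true(all(!fl$viable))
  # apparent transmission stays at the independence baseline
  ts <- timelapse_stats(sim, burn_in = 4)
  expect_true(ts$apparent)
  expect_lt(abs(ts$transmitted_fraction - ts$initial_fraction), 0.04)
})

test_that("steady-state theorem: snapshot fraction equals the recursion", {
  p <- test_params(0.15, 0.5)
  th <- implied_event_rates(p)
  oracle <- recursion_fraction(th$q)
  closed <- as.numeric(steady_state_fraction(0.15, 0.5,
                                             input = "sigma_rate"))
  expect_equal(closed, oracle, tolerance = 1e-10)
  sim <- run_simulation(sim_config(p, n_initial = 1500,
                                   n_generations = 20,
                                   population_cap = 3e4, seed = 19,
                                   record = "none"))
  pop <- sim$final_population
  fl_frac <- mean(pop$state %in% c("TRUNCATED_LINEAR",
                                   "FULL_LINEAR_WITH_ENDS"))
  expect_lt(abs(fl_frac - oracle), 0.01)
})
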