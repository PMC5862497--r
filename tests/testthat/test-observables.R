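test_that("snapshot statistics on degenerate and simulated populations", {
  pop <- new_population(200)
  set.seed(4)
  ss <- snapshot_stats(pop, map_circ, "ydeV")
  expect_equal(ss$frac_zero_focus, 0)
  expect_equal(ss$frac_zero_focus + ss$frac_one_focus +
                 ss$frac_two_focus, 1)
  expect_error(snapshot_stats(pop, map_circ, "nope"), "unknown locus")
  expect_error(snapshot_stats(pop[0, ], map_circ, "ydeV"), "empty")
})

test_that("time-lapse stats reproduce the schematic lineage worked example", {
  # 9 divisions: initial events at generations 2 and 7; the generation-2
  # event is heritable (one transmitted division at generation 3)
  ev <- data.frame(
    generation = 1:9, parent_id = 1:9,
    classification = c("NORMAL", "INITIAL", "TRANSMITTED", "NORMAL",
                       "NORMAL", "NORMAL", "INITIAL", "NORMAL", "NORMAL"),
    cleavage_pos_kb = NA_real_,
    chain = c(NA, 1L, 1L, NA, NA, NA, 2L, NA, NA),
    followup = FALSE, lost_loci = "", stringsAsFactors = FALSE)
  ts <- timelapse_stats(ev)
  expect_equal(ts$initial_fraction, 2 / 9)
  expect_equal(ts$transmitted_fraction, 1 / 2)
  expect_equal(ts$heritable_division_fraction, 1 / 9)
  expect_equal(as.integer(ts$chain_length_histogram), c(1L, 1L))
  # no events: transmission undefined, flagged as NA
  ev0 <- ev; ev0$classification <- "NORMAL"; ev0$chain <- NA_integer_
  ts0 <- timelapse_stats(ev0)
  expect_equal(ts0$initial_fraction, 0)
  expect_true(is.na(ts0$transmitted_fraction))
  expect_error(timelapse_stats(ev[0, ]), "zero divisions")
})

test_that("replication gradient copy numbers", {
  expect_equal(expected_copy_number(map_circ, c(10, 1588, 3926), 0),
               rep(1, 3))
  g <- 1.3
  expect_equal(expected_copy_number(map_circ, map_circ$ori_pos, g),
               2^g * expected_copy_number(map_circ, map_circ$dif_pos, g))
  # monotone non-increasing from ori to dif along each replichore
  cw <- seq(map_circ$ori_pos, map_circ$ori_pos +
              .Machine$double.eps + 2302, length.out = 80) %% 4641
  vals <- expected_copy_number(map_circ, cw, 1)
  expect_true(all(diff(vals) <= 1e-9))
  flat <- expected_copy_number(map_circ, c(1300, 1500, 1660), 1,
                               flatten_trap = TRUE)
  expect_equal(flat, rep(1, 3))
})

test_that("MFA self-ratio is unity within Poisson noise, scaling with depth", {
  sim <- run_quick("recB", n_initial = 400, n_generations = 12,
                   cap = 8000, seed = 23)
  pop <- sim$final_population
  set.seed(1)
  hi <- simulate_mfa(pop, pop, map_circ, bin_kb = 20, read_depth = 2e7)
  expect_lt(max(abs(hi$ratio - 1)), 0.05)
  lo <- simulate_mfa(pop, pop, map_circ, bin_kb = 20, read_depth = 2e5)
  expect_gt(sd(lo$ratio), 2 * sd(hi$ratio))  # ~ 1/sqrt(depth)
  expect_error(simulate_mfa(pop, pop, map_circ, read_depth = 0), "depth")
})

test_that("recB/wild-type MFA ratio dips at dif; ftsK trap variant spans the trap", {
  wt <- run_quick("wild_type", n_initial = 300, n_generations = 10,
                  cap = 8000, seed = 29)
  recB <- run_quick("recB", n_initial = 400, n_generations = 14,
                    cap = 8000, seed = 31)
  set.seed(2)
  mfa <- simulate_mfa(wt$final_population, recB$final_population,
                      map_circ, bin_kb = 20, read_depth = 2e7)
  lowest <- mfa$start_kb[which.min(mfa$ratio)]
  expect_lte(abs(lowest + 10 - map_circ$dif_pos), 30)  # within 1 bin of dif
  expect_lt(min(mfa$ratio), 0.85)

  trap_mut <- run_quick("matP_ftsK_dCter_recB", n_initial = 400,
                        n_generations = 14, cap = 8000, seed = 37)
  set.seed(3)
  mfa2 <- simulate_mfa(wt$final_population, trap_mut$final_population,
                       map_circ, bin_kb = 20, read_depth = 2e7)
  # the depleted region spans the fork trap: the 10 lowest bins spread over
  # hundreds of kb instead of piling on dif
  low10 <- mfa2$start_kb[order(mfa2$ratio)[1:10]]
  low10_recB <- mfa$start_kb[order(mfa$ratio)[1:10]]
  expect_gt(diff(range(low10)), 150)
  expect_lt(diff(range(low10_recB)), diff(range(low10)))
  trap <- fork_trap_interval(map_circ)
  expect_true(all(low10 > trap[1] - 250 & low10 < trap[2] + 250))
})

test_that("focus-less fraction decreases with distance from the cleavage point", {
  sim <- run_quick("recB", n_initial = 1200, n_generations = 18,
                   cap = 3e4, seed = 41)
  f <- vapply(c("ydeV", "yoaC", "ycdN"), function(l)
    frac_zero(sim, map_circ, l), 0)
  expect_true(f[["ydeV"]] > f[["yoaC"]])
  expect_true(f[["yoaC"]] > f[["ycdN"]])
  # recA_recD (helicase-only resection) is flatter in distance than recB
  simD <- run_quick("recA_recD", n_initial = 1200, n_generations = 18,
                    cap = 3e4, seed = 43)
  fD <- vapply(c("ydeV", "yoaC"), function(l)
    frac_zero(simD, map_circ, l), 0)
  expect_gt(fD[["yoaC"]] / fD[["ydeV"]], f[["yoaC"]] / f[["ydeV"]])
})

test_that("cephalexin filaments: dimer background, linear segregates", {
  wt <- cephalexin_stats(default_params("wild_type"), map_circ,
                         n_cells = 4000, seed = 5)
  expect_lt(abs(wt$nonsegregated_fraction - 0.15), 0.02)
  lin <- cephalexin_stats(default_params("wild_type"), map_lin,
                          n_cells = 4000, seed = 5)
  expect_equal(lin$nonsegregated_fraction, 0)
  # dimer-independent non-segregation tracks the sigma-formation rate
  ab <- cephalexin_stats(default_params("recA_recB"), map_circ,
                         n_cells = 8000, n_generations = 1, seed = 6)
  p_eff <- with(default_params("recA_recB"),
                p_sigma * (1 - repair_prob) * (1 - rescue_prob))
  expect_lt(abs(ab$sigma_fraction - p_eff), 0.02)
  lin2 <- cephalexin_stats(default_params("recB"), map_lin,
                           n_cells = 4000, seed = 7)
  expect_gt(lin2$focus_deficit_fraction, 0.2)  # deficit, not non-segregation
})
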