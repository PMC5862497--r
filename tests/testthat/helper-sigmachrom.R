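# shared fixtures: default maps and hand-built parameter sets

map_circ <- build_default_genome("circular")
map_lin <- build_default_genome("linear")

# minimal genotype_params with engine-relevant knobs exposed
test_params <- function(p_sigma, continuation, scale = 207,
                        repair = 0, rescue = 0,
                        first_dist = c(1, 0, 0), second_dist = c(1, 0, 0),
                        cleavage = "dif", name = "test") {
  p <- structure(list(
    name = name, p_sigma = p_sigma, repair_prob = repair,
    rescue_prob = rescue, continuation_prob = continuation,
    degradation_scale_kb = scale,
    first_division_dist = first_dist, second_division_dist = second_dist,
    hip_blocked_division = all(first_dist == c(1, 0, 0)),
    cleavage = cleavage, dimer_rate = 0.15,
    v_exo_bp_s = 850, v_fork_bp_s = 550,
    target_initial = NA_real_, target_transmitted = continuation),
    class = "genotype_params")
  p
}

# brute-force circular distance oracle: walk both arcs step-free
brute_distance <- function(a, b, L) {
  d1 <- (b - a) %% L
  d2 <- (a - b) %% L
  min(d1, d2)
}

# steady-state recursion oracle for non-dividing focus-less cells:
# d' = (d + q) / (2 - q), focus-less fraction d/(1+d) at the fixed point
recursion_fraction <- function(q, iters = 400) {
  d <- 0
  for (k in seq_len(iters)) d <- (d + q) / (2 - q)
  d / (1 + d)
}

run_quick <- function(genotype, topology = "circular", n_initial = 500,
                      n_generations = 18, cap = 2e4, seed = 1,
                      record = "none") {
  run_simulation(sim_config(genotype, topology = topology,
                            n_initial = n_initial,
                            n_generations = n_generations,
                            population_cap = cap, seed = seed,
                            record = record))
}

frac_zero <- function(sim, map, locus) {
  snapshot_stats(sim$final_population, map, locus,
                 two_focus = FALSE)$frac_zero_focus
}
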