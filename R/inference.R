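#' Wilson (or Clopper-Pearson) confidence interval for a proportion
#'
#' Wilson score intervals are the package default because the printed trial
#' counts include very small numerators (e.g. 0/31 second focus-less cells
#' with zero divisions), where Wald intervals collapse.
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @param method `"wilson"` (score interval, default) or
#'   `"clopper-pearson"` (exact, via [stats::binom.test()]).
#' @return A `rate_estimate`: list with `point`, `lower`, `upper`, `n`,
#'   `conf`, `method`.
#' @export
wilson_ci <- function(x, n, conf = 0.95,
                      method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n <= 0) stop("zero trials: no interval")
  if (x < 0 || x > n) stop("x must be in [0, n]")
  p <- x / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  } else {
    ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  structure(list(point = p, lower = lo, upper = hi, n = n,
                 conf = conf, method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f] (n = %d, %s %g%%)\n", x$point, x$lower,
              x$upper, x$n, x$method, 100 * x$conf))
  invisible(x)
}

#' Estimate initial and transmitted event rates
#'
#' From either a division-event log (see [run_simulation()] /
#' [timelapse_stats()]) or printed counts. The initial-event rate is
#' estimated over all analysed divisions; the transmission rate over initial
#' events.
#'
#' @param x Either an event `data.frame` with a `classification` column, or
#'   `NULL` when passing counts directly.
#' @param initial_count,n_divisions,transmitted_count,n_initial Counts used
#'   when `x` is `NULL`.
#' @param conf,method Passed to [wilson_ci()].
#' @return List with elements `i` and `t`, each a `rate_estimate` (`t` is
#'   `NULL` when there are no initial events).
#' @export
estimate_rates <- function(x = NULL, initial_count = NULL, n_divisions = NULL,
                           transmitted_count = NULL, n_initial = NULL,
                           conf = 0.95, method = "wilson") {
  if (!is.null(x)) {
    stopifnot(is.data.frame(x), "classification" %in% names(x))
    cl <- x$classification
    n_divisions <- sum(cl %in% c("NORMAL", "INITIAL", "TRANSMITTED"))
    initial_count <- sum(cl == "INITIAL")
    n_initial <- initial_count
    chains <- unique(x$chain[cl == "TRANSMITTED" & !is.na(x$chain)])
    transmitted_count <- length(chains)
  }
  if (is.null(n_divisions) || n_divisions <= 0)
    stop("zero divisions: nothing to estimate")
  i <- wilson_ci(initial_count, n_divisions, conf = conf, method = method)
  t <- if (!is.null(n_initial) && n_initial > 0)
    wilson_ci(transmitted_count, n_initial, conf = conf, method = method)
  list(i = i, t = t)
}

#' Heritable-division fraction
#'
#' Fraction of all divisions that belong to a heritable loss chain,
#' `h = t * i`: e.g. 0.75 x 0.177 = 0.133 for recB and 0.37 x 0.07 = 0.026
#' for recA.
#'
#' @param i Initial-event fraction (per division).
#' @param t Transmission probability (per initial event).
#' @return `h = t * i`.
#' @export
heritable_division_fraction <- function(i, t) {
  stopifnot(all(i >= 0 & i <= 1), all(t >= 0 & t <= 1))
  i * t
}

#' Per-fork breakage rate from a per-cell rate
#'
#' The default apportions the per-cell-per-generation fork breakage
#' probability equally over the two sister forks (`p/2`, i.e. 18% per cell
#' -> 9% per fork). The `"independent-forks"` option instead solves
#' `1 - (1 - x)^2 = p` for the rate of each of two independently breaking
#' forks.
#'
#' @param per_cell_rate Probability in `[0, 1]`.
#' @param method `"halved"` (default) or `"independent-forks"`.
#' @return Per-fork probability.
#' @export
per_fork_rate <- function(per_cell_rate,
                          method = c("halved", "independent-forks")) {
  method <- match.arg(method)
  stopifnot(all(per_cell_rate >= 0 & per_cell_rate <= 1))
  if (method == "halved") per_cell_rate / 2
  else 1 - sqrt(1 - per_cell_rate)
}

# Solve the steady state of the dividing (focus-carrying) population.
# Divisions are NORMAL / INITIAL / TRANSMITTED; per division,
#   q = i_obs + t*c           (initial_fraction input: i_obs over ALL divisions)
#   q = i_eff*(1-c) + t*c     (sigma_rate input: i_eff per non-carrier division)
# with carrier fraction c = q/(2-q).  Returns q, c, lambda = 2-q and both
# rate parameterizations.
.steady_core <- function(i, t, input = c("initial_fraction", "sigma_rate")) {
  input <- match.arg(input)
  stopifnot(i >= 0, i <= 1, t >= 0, t <= 1)
  if (i == 0) {
    q <- 0
  } else if (input == "initial_fraction") {
    b <- 2 + i - t
    disc <- b^2 - 8 * i
    if (disc < 0)
      stop("infeasible (i, t): no dividing-population steady state ",
           "reaches an observed initial fraction of ", i,
           " at continuation ", t)
    q <- (b - sqrt(disc)) / 2
  } else {
    b <- 2 + 2 * i - t
    disc <- b^2 - 8 * i
    if (disc < 0) stop("infeasible (sigma rate, continuation) pair")
    q <- (b - sqrt(disc)) / 2
  }
  if (q >= 1) stop("per-division loss probability q >= 1: population dies out")
  c <- q / (2 - q)
  i_obs <- q - t * c
  i_eff <- if (c < 1) i_obs / (1 - c) else NA_real_
  list(q = q, carrier_fraction = c, lambda = 2 - q,
       initial_fraction = i_obs, sigma_rate = i_eff,
       transmitted_per_division = t * c)
}

#' Closed-form event rates implied by engine parameters
#'
#' Forward map from the per-non-carrier-division sigma-formation probability
#' `p_sigma * (1-repair_prob) * (1-rescue_prob)` and the continuation
#' probability to the asymptotic observed statistics: per-division loss
#' probability `q`, carrier fraction `c = q/(2-q)`, observed initial-event
#' fraction `i_eff * (1-c)` and viable growth factor `2-q`.
#'
#' @param params A `genotype_params` object, or a bare sigma-formation rate.
#' @param continuation_prob Used when `params` is numeric.
#' @return List with `q`, `carrier_fraction`, `lambda`, `initial_fraction`,
#'   `sigma_rate`, `transmitted_per_division`.
#' @export
implied_event_rates <- function(params, continuation_prob = NULL) {
  if (inherits(params, "genotype_params")) {
    i_eff <- params$p_sigma * (1 - params$repair_prob) *
      (1 - params$rescue_prob)
    t <- params$continuation_prob
  } else {
    i_eff <- params; t <- continuation_prob
  }
  .steady_core(i_eff, t, input = "sigma_rate")
}

# expected steady-state population weight of one focus-less newborn lineage
# allowed k divisions, relative to a never-dividing newborn (mu(0) = 1),
# in a population growing by lambda per generation
.lineage_weight <- function(k, lambda) {
  r <- 2 / lambda
  j <- seq_len(k)
  (lambda - 1) * sum(r^j) + r^k
}

#' Steady-state snapshot focus-less fraction
#'
#' Closed form for the asymptotic fraction of cells in an exponentially
#' growing culture that lack a terminus locus, given the observed
#' initial-event fraction `i`, the per-generation continuation probability
#' `t` of carrier cells (geometric chains), and the division-count
#' distribution of newly born focus-less cells.
#'
#' The dividing population grows by `lambda = 2 - q` per generation, where
#' `q` is the per-division probability of producing a focus-less daughter.
#' A focus-less newborn whose lineage performs `k` divisions contributes a
#' steady-state weight `mu(k)`; the focus-less fraction is
#' `q*mu / (1 - q + q*mu)`, multiplied by the probability `loss_prob` that
#' the event actually removed the scored locus (exponential resection tail,
#' `exp(-d/scale)` at distance `d` from the cleavage point).
#'
#' @param i Initial-event fraction (default interpretation; see `input`).
#' @param t Continuation probability per generation.
#' @param first_division_dist Probability vector over 0,1,2,... divisions
#'   for first-event (truncated-chromosome) daughters.
#' @param second_division_dist Same for transmitted-event daughters.
#' @param loss_prob Probability that an event removes the scored locus.
#' @param input `"initial_fraction"` if `i` is the observed per-division
#'   initial fraction, `"sigma_rate"` if it is the per-non-carrier-division
#'   sigma-formation probability.
#' @return The predicted focus-less fraction, with the solved components
#'   (`q`, `carrier_fraction`, `lambda`, `mu`) attached as attribute
#'   `"details"`.
#' @export
steady_state_fraction <- function(i, t, first_division_dist = c(1, 0, 0),
                                  second_division_dist = first_division_dist,
                                  loss_prob = 1,
                                  input = c("initial_fraction", "sigma_rate")) {
  input <- match.arg(input)
  for (d in list(first_division_dist, second_division_dist))
    if (abs(sum(d) - 1) > 1e-8 || any(d < 0))
      stop("division distributions must be probability vectors")
  core <- .steady_core(i, t, input = input)
  q <- core$q
  if (q == 0) return(structure(0, details = core))
  lam <- core$lambda
  mu_of <- function(dist) {
    ks <- seq_along(dist) - 1
    sum(dist * vapply(ks, .lineage_weight, 0, lambda = lam))
  }
  w_init <- core$initial_fraction / q
  mu <- w_init * mu_of(first_division_dist) +
    (1 - w_init) * mu_of(second_division_dist)
  frac <- loss_prob * q * mu / (1 - q + q * mu)
  structure(frac, details = c(core, list(mu = mu)))
}

#' Fit an exponential degradation scale to locus-loss fractions
#'
#' Models the focus-less fraction at distance `d` (kb) from the cleavage
#' point as `f(d) = q * exp(-d / scale_kb)` and fits `(q, scale_kb)` by
#' least squares (closed form for exactly two points:
#' `scale = (d2 - d1) / log(f1 / f2)`).
#'
#' @param distance_kb Distances from the cleavage point (>= 2 distinct).
#' @param fraction Loss fractions in `(0, 1]`.
#' @return List with `scale_kb`, `amplitude` (the fitted `q`),
#'   `identifiable` flag (`FALSE` with `scale_kb = Inf` when the fractions
#'   do not decrease with distance) and `method`.
#' @export
fit_degradation_scale <- function(distance_kb, fraction) {
  stopifnot(length(distance_kb) == length(fraction))
  if (length(distance_kb) < 2) stop("need at least two points")
  if (anyDuplicated(distance_kb)) stop("distances must be distinct")
  if (any(fraction <= 0 | fraction > 1))
    stop("fractions must be in (0, 1]")
  o <- order(distance_kb)
  d <- distance_kb[o]; f <- fraction[o]
  if (length(d) == 2) {
    if (f[2] >= f[1])
      return(list(scale_kb = Inf, amplitude = f[1], identifiable = FALSE,
                  method = "two-point"))
    m <- (d[2] - d[1]) / log(f[1] / f[2])
    return(list(scale_kb = m, amplitude = f[1] * exp(d[1] / m),
                identifiable = TRUE, method = "two-point"))
  }
  # log-linear start, then nonlinear least squares on the raw scale
  fit0 <- stats::lm(log(f) ~ d)
  slope <- stats::coef(fit0)[["d"]]
  if (slope >= 0)
    return(list(scale_kb = Inf, amplitude = mean(f), identifiable = FALSE,
                method = "log-linear"))
  start <- list(q = exp(stats::coef(fit0)[["(Intercept)"]]), m = -1 / slope)
  fit <- tryCatch(
    stats::nls(f ~ q * exp(-d / m), start = start,
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(scale_kb = -1 / slope, amplitude = start$q,
                identifiable = TRUE, method = "log-linear"))
  cf <- stats::coef(fit)
  list(scale_kb = unname(cf["m"]), amplitude = unname(cf["q"]),
       identifiable = TRUE, method = "nls")
}

#' Model-vs-data consistency report
#'
#' For each genotype with time-lapse rates, compares the snapshot
#' focus-less fraction measured at the dif-proximal locus against (a) the
#' closed-form steady state and (b) a direct lineage-engine simulation.
#' A prediction is accepted when it falls within the larger of
#' `tol_abs` (default 6 percentage points) and `tol_sd_mult` (default 3)
#' times the measurement's standard deviation - an explicit
#' model-simplification allowance.
#'
#' @param genotypes Character vector of genotype names (default: all with
#'   time-lapse rates).
#' @param n_initial,n_generations,population_cap Simulation size knobs.
#' @param seed Integer seed (one simulation per genotype).
#' @param tol_abs,tol_sd_mult Acceptance tolerances.
#' @param locus Scored locus (default `"ydeV"`).
#' @return `data.frame` with observed, predicted (closed-form and
#'   simulated) fractions, `h`, and verdict columns.
#' @export
consistency_report <- function(genotypes = NULL, n_initial = 500,
                               n_generations = 25, population_cap = 20000,
                               seed = 1, tol_abs = 0.06, tol_sd_mult = 3,
                               locus = "ydeV") {
  tab <- genotype_table()
  if (is.null(genotypes))
    genotypes <- tab$genotype[!is.na(tab$initial) & tab$initial > 0 &
                                !is.na(tab$snap_ydeV)]
  map <- build_default_genome()
  rows <- lapply(seq_along(genotypes), function(k) {
    g <- genotypes[k]
    p <- default_params(g)
    obs <- tab$snap_ydeV[tab$genotype == g] / 100
    obs_sd <- tab$snap_ydeV_sd[tab$genotype == g] / 100
    d <- genome_distance(map, map$loci[[locus]], map$dif_pos)
    ploss <- exp(-d / p$degradation_scale_kb)
    pred_cf <- as.numeric(steady_state_fraction(
      p$target_initial, p$continuation_prob,
      first_division_dist = p$first_division_dist,
      second_division_dist = p$second_division_dist,
      loss_prob = ploss))
    sim <- run_simulation(sim_config(
      genotype = g, n_initial = n_initial, n_generations = n_generations,
      population_cap = population_cap, seed = seed + k, record = "none"))
    ss <- snapshot_stats(sim$final_population, map, locus,
                         two_focus = FALSE)
    h <- heritable_division_fraction(p$target_initial, p$continuation_prob)
    tol <- max(tol_abs, tol_sd_mult * ifelse(is.na(obs_sd), 0, obs_sd))
    data.frame(
      genotype = g, observed = obs, observed_sd = obs_sd,
      predicted_closed_form = pred_cf,
      predicted_simulated = ss$frac_zero_focus,
      simulated_mc_se = sqrt(ss$frac_zero_focus *
                               (1 - ss$frac_zero_focus) / ss$n_cells),
      h = h, tolerance = tol,
      closed_form_ok = abs(pred_cf - obs) <= tol,
      simulated_ok = abs(ss$frac_zero_focus - obs) <= tol,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
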