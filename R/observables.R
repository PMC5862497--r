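#' Snapshot focus statistics for one locus
#'
#' Mirrors the snapshot microscopy readout: the fraction of cells with
#' zero, one or two fluorescent foci at a parS-tagged locus. Zero-focus
#' cells are those whose lost arc covers the locus. Among locus-retaining
#' cells, the two-focus fraction models replication-and-segregation as a
#' Bernoulli draw whose probability is the replication-timing excess
#' `2^(g*(1-tau)) - 1` scaled by `seg_prob` (earlier-replicating loci are
#' more often visibly doubled); it consumes RNG draws when
#' `two_focus = TRUE`.
#'
#' @param pop Population `data.frame` (e.g. `sim$final_population`).
#' @param map A [genome_map()].
#' @param locus Locus name.
#' @param growth_exponent Overlapping-round exponent `g` (default 1).
#' @param seg_prob Probability a replicated locus is visibly segregated.
#' @param two_focus Draw the one/two-focus split (default `TRUE`).
#' @param conf Confidence level of the Wilson interval on the zero-focus
#'   fraction.
#' @return List of class `snapshot_stats`: `locus`, `n_cells`,
#'   `frac_zero_focus`, `frac_one_focus`, `frac_two_focus`, `ci95`.
#' @export
snapshot_stats <- function(pop, map, locus, growth_exponent = 1,
                           seg_prob = 0.8, two_focus = TRUE, conf = 0.95) {
  if (nrow(pop) == 0) stop("empty population")
  present <- locus_present(pop, map, locus)
  n <- nrow(pop)
  f0 <- mean(!present)
  if (two_focus) {
    p2 <- seg_prob *
      (expected_copy_number(map, map$loci[[locus]], growth_exponent) - 1)
    two <- stats::runif(sum(present)) < p2
    f2 <- sum(two) / n
  } else f2 <- 0
  structure(list(locus = locus, n_cells = n, frac_zero_focus = f0,
                 frac_one_focus = 1 - f0 - f2, frac_two_focus = f2,
                 ci95 = wilson_ci(round(f0 * n), n, conf = conf)),
            class = "snapshot_stats")
}

#' @export
print.snapshot_stats <- function(x, ...) {
  cat(sprintf("<snapshot_stats> %s: n = %d | 0 focus %.3f [%.3f, %.3f] | 1 focus %.3f | 2 foci %.3f\n",
              x$locus, x$n_cells, x$frac_zero_focus, x$ci95$lower,
              x$ci95$upper, x$frac_one_focus, x$frac_two_focus))
  invisible(x)
}

#' Time-lapse event statistics
#'
#' Computes the initial-event fraction (initial events over all analysed
#' divisions, transmitted divisions included in the denominator, matching
#' the time-lapse counting rule), the transmission probability (initial
#' events followed by at least one transmitted event), and the
#' heritable-division fraction `h = t * i`. For linear-topology runs, where
#' no carrier chains exist, the *apparent* transmission (an event at the
#' very next division of the focus-retaining daughter, i.e. the
#' independence baseline) is reported as `transmitted_fraction`.
#'
#' @param x A `sigma_sim` or an event `data.frame` (columns
#'   `classification`, `chain`, optionally `followup`).
#' @param burn_in Drop divisions from generations `<= burn_in` (requires a
#'   `generation` column); default 0.
#' @return List of class `timelapse_stats`: `n_divisions`,
#'   `initial_fraction`, `transmitted_fraction`,
#'   `heritable_division_fraction`, `chain_length_histogram`,
#'   `apparent` (logical: transmission is the independence baseline).
#' @export
timelapse_stats <- function(x, burn_in = 0) {
  if (inherits(x, "sigma_sim")) {
    pg <- x$per_generation
    pg <- pg[pg$generation > burn_in, , drop = FALSE]
    n_div <- sum(pg$n_divisions)
    n_init <- sum(pg$n_initial)
    n_trans <- sum(pg$n_transmitted)
    ev <- x$events
    ev <- ev[ev$generation > burn_in, , drop = FALSE]
    linear <- x$config$topology == "linear"
    # transmission measured on monitored next divisions of focus-retaining
    # daughters (unbiased under population down-sampling): the continuation
    # probability for circular chromosomes, the independence baseline for
    # linear ones
    n_watch <- sum(pg$n_watched)
    t_frac <- if (n_watch > 0) sum(pg$n_followup) / n_watch else NA_real_
    hist <- if (!linear)
      .chain_hist(ev$chain[ev$classification == "INITIAL"],
                  ev$chain[ev$classification == "TRANSMITTED"])
    else NULL
  } else {
    stopifnot(is.data.frame(x), "classification" %in% names(x))
    if (burn_in > 0 && "generation" %in% names(x))
      x <- x[x$generation > burn_in, , drop = FALSE]
    cl <- x$classification
    n_div <- sum(cl %in% c("NORMAL", "INITIAL", "TRANSMITTED"))
    n_init <- sum(cl == "INITIAL")
    n_trans <- sum(cl == "TRANSMITTED")
    linear <- n_trans == 0 && "followup" %in% names(x) && any(x$followup)
    chains_i <- x$chain[cl == "INITIAL"]
    chains_t <- x$chain[cl == "TRANSMITTED"]
    n_init_watchable <- if ("generation" %in% names(x) && nrow(x) > 0)
      sum(cl == "INITIAL" & x$generation < max(x$generation)) else n_init
    t_frac <- if (n_init == 0) NA_real_
              else if (linear)
                sum(x$followup[cl == "INITIAL"]) /
                  max(1L, n_init_watchable)
              else length(unique(chains_t)) / n_init
    hist <- if (!linear) .chain_hist(chains_i, chains_t) else NULL
  }
  if (n_div == 0) stop("zero divisions")
  i_frac <- n_init / n_div
  structure(list(n_divisions = n_div, n_initial = n_init,
                 initial_fraction = i_frac,
                 transmitted_fraction = t_frac,
                 heritable_division_fraction =
                   if (is.na(t_frac)) NA_real_ else i_frac * t_frac,
                 chain_length_histogram = hist,
                 apparent = isTRUE(linear)),
            class = "timelapse_stats")
}

# transmitted events per initial chain -> histogram of chain lengths
.chain_hist <- function(chains_i, chains_t) {
  if (!length(chains_i)) return(NULL)
  table(tabulate(factor(chains_t, levels = unique(chains_i)),
                 nbins = length(unique(chains_i))))
}

#' @export
print.timelapse_stats <- function(x, ...) {
  cat(sprintf("<timelapse_stats> %d divisions | initial %.3f | %s %s | h %.3f\n",
              x$n_divisions, x$initial_fraction,
              if (x$apparent) "apparent transmitted" else "transmitted",
              ifelse(is.na(x$transmitted_fraction), "NA (no initial events)",
                     sprintf("%.3f", x$transmitted_fraction)),
              x$heritable_division_fraction))
  invisible(x)
}

#' Expected relative copy number under an exponential replication gradient
#'
#' In an exponentially growing culture the expected copy number of a locus
#' decreases from origin to terminus: `2^(g * (1 - tau(x)))`, where
#' `tau(x)` is the relative replication time of `x` (distance from *oriC*
#' along its replichore divided by the replichore length) and `g` is the
#' number of overlapping replication rounds.
#'
#' @param map A [genome_map()].
#' @param x Position(s) in kb.
#' @param growth_exponent `g >= 0`; 0 means a non-replicating population.
#' @param flatten_trap If `TRUE`, positions inside the fork trap all take
#'   the terminal value (`tau = 1`), emulating the *ter* pause.
#' @return Copy number relative to a terminus value of 1.
#' @export
expected_copy_number <- function(map, x, growth_exponent = 1,
                                 flatten_trap = FALSE) {
  if (any(x < 0 | x >= map$length_kb)) stop("positions out of range")
  L <- map$length_kb
  cw_len <- .arc_len(map$ori_pos, map$dif_pos, L)   # ori -> dif increasing
  ccw_len <- L - cw_len
  d_cw <- .arc_len(map$ori_pos, x, L)               # along increasing arc
  on_cw <- d_cw <= cw_len
  tau <- ifelse(on_cw, d_cw / cw_len, (L - d_cw) / ccw_len)
  if (flatten_trap) tau[in_fork_trap(map, x)] <- 1
  2^(growth_exponent * (1 - tau))
}

#' Binned expected coverage profile of a population
#'
#' Per-bin expected marker frequency: replication-gradient copy number
#' times the number of cells retaining the bin, normalized to sum to 1
#' (read frequencies normalized to the total number of reads).
#'
#' @param pop Population `data.frame`.
#' @param map A [genome_map()].
#' @param bin_kb Bin width in kb (default 1).
#' @param growth_exponent Replication gradient exponent.
#' @return Object of class `coverage_profile`: `data.frame` with
#'   `start_kb`, `end_kb`, `value` (sums to 1) plus the map as attribute.
#' @export
coverage_profile <- function(pop, map, bin_kb = 1, growth_exponent = 1) {
  L <- map$length_kb
  nb <- ceiling(L / bin_kb)
  mids <- (seq_len(nb) - 0.5) * bin_kb
  mids[mids >= L] <- L - 1e-9
  copies <- expected_copy_number(map, mids, growth_exponent)
  # count of cells having lost each bin, via a difference array
  lost <- numeric(nb + 1L)
  has_loss <- which(!is.na(pop$lost_a))
  if (length(has_loss)) {
    a <- pop$lost_a[has_loss]; b <- pop$lost_b[has_loss]
    ia <- pmin(nb, floor(a / bin_kb) + 1L)
    ib <- pmin(nb, floor(b / bin_kb) + 1L)
    wrap <- ia > ib
    add_seg <- function(from, to) {
      for (k in seq_along(from)) {
        lost[from[k]] <<- lost[from[k]] + 1
        lost[to[k] + 1L] <<- lost[to[k] + 1L] - 1
      }
    }
    add_seg(ia[!wrap], ib[!wrap])
    if (any(wrap)) {
      add_seg(ia[wrap], rep(nb, sum(wrap)))
      add_seg(rep(1L, sum(wrap)), ib[wrap])
    }
  }
  n_lost <- cumsum(lost[seq_len(nb)])
  cov <- copies * pmax(0, nrow(pop) - n_lost)
  val <- cov / sum(cov)
  structure(data.frame(start_kb = (seq_len(nb) - 1) * bin_kb,
                       end_kb = pmin(seq_len(nb) * bin_kb, L),
                       value = val),
            class = c("coverage_profile", "data.frame"),
            map = map, bin_kb = bin_kb)
}

#' Simulated marker frequency analysis (MFA) ratio
#'
#' Emulates the sequencing readout: Poisson read counts are drawn per bin
#' for each population's normalized expected coverage, re-normalized, and
#' the per-bin ratio taken (`B/A` by default, i.e. mutant over wild-type
#' plotted as a dip below 1 in the mutant terminus).
#'
#' @param popA,popB Population `data.frame`s simulated on the same map
#'   (A = reference/wild-type orientation).
#' @param map A [genome_map()].
#' @param bin_kb Bin width (default 10 kb).
#' @param read_depth Total expected reads per library.
#' @param growth_exponent Replication gradient exponent.
#' @param orientation `"B_over_A"` (default) or `"A_over_B"`.
#' @param dispersion Optional negative-binomial size parameter; `Inf`
#'   (default) gives pure Poisson noise.
#' @return `data.frame` with `start_kb`, `end_kb`, `ratio`, `countA`,
#'   `countB`; the two normalized profiles are attached as attributes.
#' @export
simulate_mfa <- function(popA, popB, map, bin_kb = 10, read_depth = 1e6,
                         growth_exponent = 1,
                         orientation = c("B_over_A", "A_over_B"),
                         dispersion = Inf) {
  orientation <- match.arg(orientation)
  if (read_depth <= 0) stop("zero read depth")
  profA <- coverage_profile(popA, map, bin_kb, growth_exponent)
  profB <- coverage_profile(popB, map, bin_kb, growth_exponent)
  if (nrow(profA) != nrow(profB)) stop("bin mismatch")
  draw <- function(mu) {
    if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = dispersion, mu = mu)
  }
  cA <- draw(read_depth * profA$value)
  cB <- draw(read_depth * profB$value)
  nA <- cA / sum(cA); nB <- cB / sum(cB)
  ratio <- if (orientation == "B_over_A") nB / nA else nA / nB
  structure(data.frame(start_kb = profA$start_kb, end_kb = profA$end_kb,
                       ratio = ratio, countA = cA, countB = cB),
            profileA = profA, profileB = profB, map = map)
}

#' Division-blocked (cephalexin) segregation statistics
#'
#' Emulates scoring filaments after blocking septation: division is
#' disabled for `n_generations` while sigma-chromosome formation stays
#' active. A filament shows a non-segregated dif-proximal locus if it holds
#' a sigma-replicating chromosome at sampling or carries an unresolved
#' chromosome dimer (background `dimer_rate`, circular chromosomes only;
#' the two are combined as independent events). On linear chromosomes
#' dimers cannot form and sigma-carriers present a focus deficit instead,
#' reported separately.
#'
#' @param params A `genotype_params`.
#' @param map A [genome_map()].
#' @param n_cells Number of filaments scored.
#' @param n_generations Sampling window (replication rounds with division
#'   blocked), default 2.
#' @param seed Integer seed.
#' @return List: `nonsegregated_fraction`, `sigma_fraction`,
#'   `dimer_fraction`, `focus_deficit_fraction` (linear), `ci95`.
#' @export
cephalexin_stats <- function(params, map, n_cells = 5000,
                             n_generations = 2, seed = 1) {
  set.seed(seed)
  p_eff <- params$p_sigma * (1 - params$repair_prob) *
    (1 - params$rescue_prob)
  sigma <- rep(FALSE, n_cells)
  for (g in seq_len(n_generations))
    sigma <- sigma | (stats::runif(n_cells) < p_eff)
  linear <- map$topology == "linear"
  dimer <- if (linear) rep(FALSE, n_cells)
           else stats::runif(n_cells) < params$dimer_rate
  if (linear) {
    nonseg <- rep(FALSE, n_cells)
    deficit <- sigma
  } else {
    nonseg <- sigma | dimer
    deficit <- rep(FALSE, n_cells)
  }
  list(nonsegregated_fraction = mean(nonseg),
       sigma_fraction = mean(sigma),
       dimer_fraction = mean(dimer),
       focus_deficit_fraction = mean(deficit),
       ci95 = wilson_ci(sum(nonseg), n_cells))
}
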