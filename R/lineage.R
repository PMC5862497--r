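#' Create a founding population of intact cells
#'
#' The population is a plain `data.frame`, one row per cell:
#' `id`, `born` (generation of birth), `state` (`INTACT`, `SIGMA`,
#' `TRUNCATED_LINEAR`, `FULL_LINEAR_WITH_ENDS`), `carrier` (sigma-chromosome
#' with a short post-cleavage tail, will repeat the loss with the
#' continuation probability), `chain` (heritable-chain id), `watch`
#' (event id whose follow-up division is being monitored, linear topology),
#' `viable`, `div_rem` (residual divisions of focus-less cells; `NA` for
#' normal dividers), and the lost genomic arc `lost_a` -> `lost_b`
#' (increasing circular arc, `NA` when the genome is complete).
#'
#' @param n Number of founding cells.
#' @return Population `data.frame`.
#' @export
new_population <- function(n) {
  data.frame(id = seq_len(n), born = 0L, state = "INTACT",
             carrier = FALSE, chain = NA_integer_, watch = NA_integer_,
             viable = TRUE, div_rem = NA_integer_,
             lost_a = NA_real_, lost_b = NA_real_,
             stringsAsFactors = FALSE)
}

#' Septum cleavage position for a loss event
#'
#' FtsK-proficient genotypes translocate KOPS-oriented DNA so that the
#' septum closes exactly on *dif*; `cleavage = "trap"` genotypes
#' (FtsK C-terminal deletions) cleave uniformly over the fork-trap
#' interval. On linear chromosomes resolution happens at the *tos* site
#' (TelN), with no septum-induced break.
#'
#' @param params A `genotype_params`.
#' @param map A [genome_map()].
#' @param n Number of positions to draw.
#' @return Numeric vector of kb positions (consumes `n` RNG draws only for
#'   `"trap"` cleavage).
#' @export
cleavage_position <- function(params, map, n = 1) {
  if (map$topology == "linear") return(rep(map$tos_pos, n))
  if (identical(params$cleavage, "trap")) {
    trap <- fork_trap_interval(map)
    stats::runif(n, trap[1], trap[2])
  } else {
    rep(map$dif_pos, n)
  }
}

# draw division budgets from a 0/1/2/... distribution
.draw_divisions <- function(n, dist) {
  if (n == 0) return(integer(0))
  sample.int(length(dist), n, replace = TRUE, prob = dist) - 1L
}

#' Exponential end resection of free double-strand ends
#'
#' For each free end of a cell's lost arc, draws an extent from
#' `Exponential(mean = degradation_scale_kb)` and removes that much DNA
#' inward. The lost arc grows monotonically; protected (hairpin) ends on
#' linear chromosomes are not resected.
#'
#' @param cells Population rows with free ends (`lost_a`/`lost_b` set).
#' @param params A `genotype_params`.
#' @param map A [genome_map()].
#' @param ends `"both"`, `"left"` (extend `lost_a` downward) or `"right"`.
#' @return The rows with updated lost arcs.
#' @export
degrade_ends <- function(cells, params, map, ends = "both") {
  n <- nrow(cells)
  if (n == 0) return(cells)
  scale <- params$degradation_scale_kb
  L <- map$length_kb
  draw <- function(k) if (scale <= 0) numeric(k) else stats::rexp(k, rate = 1 / scale)
  room <- function() L - 1e-6 - .arc_len(cells$lost_a, cells$lost_b, L)
  if (ends %in% c("both", "left")) {
    ext <- pmin(draw(n), room())  # cap: never lose more than the genome
    cells$lost_a <- (cells$lost_a - ext) %% L
  }
  if (ends %in% c("both", "right")) {
    ext <- pmin(draw(n), room())
    cells$lost_b <- (cells$lost_b + ext) %% L
  }
  cells
}

.empty_events <- function() {
  data.frame(generation = integer(0), parent_id = integer(0),
             classification = character(0), cleavage_pos_kb = numeric(0),
             chain = integer(0), followup = logical(0),
             lost_loci = character(0), stringsAsFactors = FALSE)
}

.lost_loci_string <- function(map, lost_a, lost_b) {
  if (!length(lost_a)) return(character(0))
  out <- character(length(lost_a))
  for (k in seq_along(lost_a)) {
    lost <- names(map$loci)[.in_arc(map$loci, lost_a[k], lost_b[k],
                                    map$length_kb)]
    out[k] <- paste(lost, collapse = ";")
  }
  out
}

#' Advance a population by one replication-division cycle
#'
#' Implements the sigma-chromosome state machine. Per generation every
#' viable cell (and every focus-less cell with residual divisions) divides
#' once:
#' * intact non-carrier: with probability
#'   `p_sigma * (1 - repair_prob)` a sigma-replicating chromosome forms;
#'   with `rescue_prob` Exo V degrades the whole tail and the event aborts;
#'   otherwise septum closure cleaves the tail (see [cleavage_position()]),
#'   producing one focus-less daughter (`TRUNCATED_LINEAR`) and one carrier;
#' * carrier: with `continuation_prob` the loss repeats (TRANSMITTED event,
#'   `FULL_LINEAR_WITH_ENDS` daughter); otherwise the cell reverts to a
#'   normal division;
#' * focus-less cells with `div_rem > 0` produce two focus-less daughters
#'   inheriting `div_rem - 1` and the lost arc;
#' * linear topology: the broken-fork dimer is resolved at *tos* by TelN,
#'   the surviving daughter is never a carrier, and daughters losing the
#'   *hipAB*-containing end are non-viable and non-dividing.
#'
#' RNG draw order (single stream): breakage, rescue, continuation, cleavage
#' positions, degradation extents (left then right ends in parent order),
#' division-count draws (initial then transmitted daughters).
#'
#' @param pop Population `data.frame` (see [new_population()]).
#' @param params A `genotype_params`.
#' @param map A [genome_map()].
#' @param generation Integer generation index recorded in the event log.
#' @param record `"all"` (NORMAL rows included), `"events"` or `"none"`.
#' @param next_id,next_chain Id counters (defaults derived from `pop`).
#' @return List with `population`, `events`, `counts` (one-row summary),
#'   `next_id`, `next_chain`.
#' @export
step_generation <- function(pop, params, map, generation = 1L,
                            record = "all",
                            next_id = max(pop$id) + 1L, next_chain = 1L) {
  if (nrow(pop) == 0) stop("empty population")
  L <- map$length_kb
  linear <- map$topology == "linear"

  is_fl <- pop$state %in% c("TRUNCATED_LINEAR", "FULL_LINEAR_WITH_ENDS")
  idx_norm <- which(pop$viable & !is_fl & !pop$carrier)
  idx_car <- which(pop$viable & !is_fl & pop$carrier)
  idx_fl_div <- which(is_fl & !is.na(pop$div_rem) & pop$div_rem > 0L)
  idx_rest <- setdiff(seq_len(nrow(pop)), c(idx_norm, idx_car, idx_fl_div))

  p_break <- params$p_sigma * (1 - params$repair_prob)

  # --- draws (documented order) ---
  u_break <- stats::runif(length(idx_norm))
  broke <- u_break < p_break
  u_resc <- stats::runif(sum(broke))
  kept <- u_resc >= params$rescue_prob
  ev_init <- idx_norm[broke][kept]
  u_cont <- stats::runif(length(idx_car))
  ev_trans <- if (linear) integer(0) else idx_car[u_cont < params$continuation_prob]
  idx_car_norm <- setdiff(idx_car, ev_trans)

  n_init <- length(ev_init); n_trans <- length(ev_trans)
  ev_all <- c(ev_init, ev_trans)
  n_ev <- n_init + n_trans

  if (linear && n_ev > 0) {
    # side of the broken fork: right = hipAB/ydeV side of tos
    side_right <- stats::runif(n_ev) < 0.5
    arc_r <- .arc_len(map$tos_pos, map$ori_pos, L)
    arc_l <- L - arc_r
    u_x <- stats::runif(n_ev)
    x <- ifelse(side_right,
                (map$tos_pos + u_x * arc_r) %% L,
                (map$ori_pos + u_x * arc_l) %% L)
    ext <- if (params$degradation_scale_kb <= 0) numeric(n_ev)
           else stats::rexp(n_ev, 1 / params$degradation_scale_kb)
    # cap so the lost arc never exceeds the genome
    trunc_len <- ifelse(side_right, .arc_len(map$tos_pos, x, L),
                        .arc_len(x, map$tos_pos, L))
    ext <- pmin(ext, L - 1e-6 - trunc_len)
    lost_a <- ifelse(side_right, map$tos_pos, (x - ext) %% L)
    lost_b <- ifelse(side_right, (x + ext) %% L, map$tos_pos)
    cleave <- rep(map$tos_pos, n_ev)
  } else if (n_ev > 0) {
    cleave <- cleavage_position(params, map, n_ev)
    ext_l <- if (params$degradation_scale_kb <= 0) numeric(n_ev)
             else stats::rexp(n_ev, 1 / params$degradation_scale_kb)
    ext_r <- if (params$degradation_scale_kb <= 0) numeric(n_ev)
             else stats::rexp(n_ev, 1 / params$degradation_scale_kb)
    # cap before modular arithmetic: at most the whole genome is lost
    tot <- ext_l + ext_r
    f <- ifelse(tot >= L - 1e-6, (L - 1e-6) / pmax(tot, 1e-12), 1)
    ext_l <- ext_l * f; ext_r <- ext_r * f
    lost_a <- (cleave - ext_l) %% L
    lost_b <- (cleave + ext_r) %% L
  }

  # division budgets for the focus-less daughters
  if (n_ev > 0) {
    if (linear) {
      hip_lost <- .in_arc(map$hip_pos, lost_a, lost_b, L)
      k_div <- integer(n_ev)
      # hipAB retained: divide per the focus-less distribution without the
      # immediate-failure (zero-division) term
      d1 <- params$first_division_dist
      if (sum(d1[-1]) > 0) d1 <- c(0, d1[-1] / sum(d1[-1]))
      k_div[!hip_lost] <- .draw_divisions(sum(!hip_lost), d1)
    } else {
      k_init <- .draw_divisions(n_init, params$first_division_dist)
      k_trans <- .draw_divisions(n_trans, params$second_division_dist)
      k_div <- c(k_init, k_trans)
    }
  }

  # --- assemble daughters ---
  blank <- function(n, state = "INTACT") {
    data.frame(id = seq.int(next_id, length.out = n), born = generation,
               state = state, carrier = FALSE, chain = NA_integer_,
               watch = NA_integer_, viable = TRUE, div_rem = NA_integer_,
               lost_a = NA_real_, lost_b = NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list(); evl <- list()

  # normal divisions (no event, rescued events, reverting carriers)
  idx_normal_div <- c(setdiff(idx_norm, ev_init), idx_car_norm)
  n_nd <- length(idx_normal_div)
  if (n_nd > 0) {
    d <- blank(2L * n_nd)
    next_id <- next_id + 2L * n_nd
    out[[length(out) + 1L]] <- d
    if (record == "all") {
      evl[[length(evl) + 1L]] <- data.frame(
        generation = generation, parent_id = pop$id[idx_normal_div],
        classification = "NORMAL", cleavage_pos_kb = NA_real_,
        chain = NA_integer_, followup = FALSE, lost_loci = "",
        stringsAsFactors = FALSE)
    }
  }

  if (n_ev > 0) {
    chains <- c(if (n_init) seq.int(next_chain, length.out = n_init)
                else integer(0),
                pop$chain[ev_trans])
    next_chain <- next_chain + n_init
    # surviving (focus-retaining) daughters
    surv <- blank(n_ev)
    next_id <- next_id + n_ev
    if (!linear) {
      surv$state <- "SIGMA"  # circle plus short post-cleavage tail
      surv$carrier <- TRUE
      surv$chain <- chains
    }
    # monitor the focus-retaining daughter's next division: its event
    # probability is the continuation (circular) or the independence
    # baseline (linear); conditioning on the daughter's survival keeps the
    # estimate unbiased under population down-sampling
    surv$watch <- seq_len(n_ev)
    # focus-less daughters
    fl <- blank(n_ev, state = c(rep("TRUNCATED_LINEAR", n_init),
                                rep("FULL_LINEAR_WITH_ENDS", n_trans)))
    next_id <- next_id + n_ev
    fl$viable <- FALSE
    fl$div_rem <- k_div
    fl$lost_a <- lost_a
    fl$lost_b <- lost_b
    fl$chain <- chains
    if (linear) fl$state <- "TRUNCATED_LINEAR"
    out[[length(out) + 1L]] <- surv
    out[[length(out) + 1L]] <- fl
    if (record %in% c("all", "events")) {
      evl[[length(evl) + 1L]] <- data.frame(
        generation = generation, parent_id = pop$id[ev_all],
        classification = c(rep("INITIAL", n_init),
                           rep("TRANSMITTED", n_trans)),
        cleavage_pos_kb = cleave, chain = chains,
        followup = !is.na(pop$watch[ev_all]),
        lost_loci = .lost_loci_string(map, lost_a, lost_b),
        stringsAsFactors = FALSE)
    }
  }

  # focus-less divisions: two focus-less daughters, budget - 1
  n_fd <- length(idx_fl_div)
  if (n_fd > 0) {
    par <- pop[idx_fl_div, ]
    d <- par[rep(seq_len(n_fd), each = 2L), ]
    d$id <- seq.int(next_id, length.out = 2L * n_fd)
    next_id <- next_id + 2L * n_fd
    d$born <- generation
    d$div_rem <- d$div_rem - 1L
    d$watch <- NA_integer_
    rownames(d) <- NULL
    out[[length(out) + 1L]] <- d
  }

  # follow-up bookkeeping (one-generation watch after any event)
  watched_div <- !is.na(pop$watch)
  followups <- sum(!is.na(pop$watch[ev_all]))

  carry <- pop[idx_rest, ]
  if (nrow(carry)) carry$watch <- NA_integer_
  new_pop <- do.call(rbind, c(list(carry), out))
  rownames(new_pop) <- NULL

  events <- if (length(evl)) do.call(rbind, evl) else .empty_events()
  counts <- data.frame(
    generation = generation,
    n_cells = nrow(new_pop),
    n_divisions = n_nd + n_ev,
    n_focusless_divisions = n_fd,
    n_initial = n_init, n_transmitted = n_trans,
    n_watched = sum(watched_div), n_followup = followups,
    n_focusless = sum(new_pop$state != "INTACT" & !new_pop$carrier))
  list(population = new_pop, events = events, counts = counts,
       next_id = next_id, next_chain = next_chain)
}

#' Simulation configuration
#'
#' @param genotype Genotype label (see [list_genotypes()]) or a
#'   `genotype_params` object.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param n_initial Founding population size.
#' @param n_generations Number of replication-division cycles.
#' @param seed Mandatory integer seed (no silent nondeterminism).
#' @param population_cap Uniform down-sampling bound (default 1e5);
#'   down-sampling is unbiased for all reported fractions.
#' @param record `"all"`, `"events"` (default; NORMAL divisions are only
#'   tallied) or `"none"`.
#' @param map Optional custom [genome_map()].
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(genotype, topology = c("circular", "linear"),
                       n_initial = 100, n_generations = 10, seed = 1,
                       population_cap = 1e5, record = c("events", "all", "none"),
                       map = NULL) {
  topology <- match.arg(topology)
  record <- match.arg(record)
  params <- if (inherits(genotype, "genotype_params")) genotype
            else default_params(genotype)
  bad <- c(n_initial <= 0, n_generations < 0, population_cap < 1,
           is.null(seed) || is.na(seed))
  if (any(bad))
    stop("invalid config field(s): ",
         paste(c("n_initial", "n_generations", "population_cap",
                 "seed")[bad], collapse = ", "))
  if (is.null(map)) map <- build_default_genome(topology)
  if (map$topology != topology) stop("map topology mismatch")
  structure(list(params = params, topology = topology,
                 n_initial = as.integer(n_initial),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed),
                 population_cap = as.integer(population_cap),
                 record = record, map = map),
            class = "sim_config")
}

#' Run a seeded lineage simulation
#'
#' Deterministic given the seed: repeated runs with an identical
#' [sim_config()] return identical results. The population is uniformly
#' down-sampled to `population_cap` after each generation; per-generation
#' tallies are recorded before down-sampling so event fractions are
#' unbiased.
#'
#' @param config A [sim_config()].
#' @return Object of class `sigma_sim`: `final_population`, `events`,
#'   `per_generation` (counts table), `config`.
#' @examples
#' sim <- run_simulation(sim_config("recB", n_initial = 50,
#'                                  n_generations = 6, seed = 42))
#' timelapse_stats(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pop <- new_population(config$n_initial)
  next_id <- config$n_initial + 1L
  next_chain <- 1L
  evl <- list(); ctl <- list()
  g <- 0L
  while (g < config$n_generations) {
    g <- g + 1L
    st <- step_generation(pop, config$params, config$map, generation = g,
                          record = config$record, next_id = next_id,
                          next_chain = next_chain)
    pop <- st$population
    next_id <- st$next_id; next_chain <- st$next_chain
    if (config$record != "none" && nrow(st$events))
      evl[[length(evl) + 1L]] <- st$events
    ctl[[length(ctl) + 1L]] <- st$counts
    if (nrow(pop) > config$population_cap) {
      keep <- sample.int(nrow(pop), config$population_cap)
      pop <- pop[sort(keep), ]
      rownames(pop) <- NULL
    }
  }
  events <- if (length(evl)) do.call(rbind, evl) else .empty_events()
  per_gen <- if (length(ctl)) do.call(rbind, ctl) else NULL
  structure(list(final_population = pop, events = events,
                 per_generation = per_gen, config = config),
            class = "sigma_sim")
}

#' @export
print.sigma_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sigma_sim> %s, %s, %d generations, seed %d\n",
              cfg$params$name, cfg$topology, cfg$n_generations, cfg$seed))
  cat(sprintf("  final population %d cells (%d focus-less)\n",
              nrow(x$final_population),
              sum(x$final_population$state %in%
                    c("TRUNCATED_LINEAR", "FULL_LINEAR_WITH_ENDS"))))
  if (!is.null(x$per_generation)) {
    tot <- colSums(x$per_generation[, c("n_divisions", "n_initial",
                                        "n_transmitted")])
    cat(sprintf("  divisions %d | initial %d | transmitted %d\n",
                tot[1], tot[2], tot[3]))
  }
  invisible(x)
}

#' Is a locus present (visible as a focus) in each cell?
#'
#' @param pop Population `data.frame` or a single-cell row.
#' @param map A [genome_map()].
#' @param locus Locus name in `map$loci`.
#' @return Logical vector, `TRUE` where the locus lies in retained DNA.
#' @export
locus_present <- function(pop, map, locus) {
  if (!locus %in% names(map$loci)) stop("unknown locus: ", locus)
  x <- map$loci[[locus]]
  ok <- is.na(pop$lost_a)
  ifelse(ok, TRUE, !.in_arc(x, pop$lost_a, pop$lost_b, map$length_kb))
}
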