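# Measured per-genotype rates: snapshot focus-less percentages (mean, sd),
# time-lapse initial-event and transmission percentages, and structural
# flags.  Rates are stored as measured; the stochastic engine parameters
# (p_sigma, rescue_prob, degradation scale) are derived at run time by
# closed-form calibration so that the simulated observables reproduce the
# measured ones.
.genotype_rows <- list(
  #            initial transm  base  ydeV  sd   yoaC  sd    ycdN cleav  divide repair_like
  wild_type  = list(0,    0,    NA,   0.6,  0.2, 0.6,  0.3,  NA, "dif", FALSE, "repair"),
  recD       = list(0,    0,    NA,   0.6,  0.7, 0.34, 0.37, NA, "dif", FALSE, "repair"),
  sbcB_sbcD  = list(0,    0,    NA,   1.0,  0.1, 1.7,  0.8,  NA, "dif", FALSE, "repair"),
  recB       = list(17.7, 74.5, NA,   32,   1.5, 7.9,  1,    NA, "dif", FALSE, "none"),
  recA       = list(7.0,  37.2, 21,   9,    2.8, 8.8,  0.9,  NA, "dif", FALSE, "rescue"),
  recA_recB  = list(21,   83.7, NA,   36.6, 1.5, 8.5,  1.6,  NA, "dif", FALSE, "none"),
  recA_recD  = list(16.1, 65,   NA,   27.3, 2.1, 23,   2.1,  11, "dif", FALSE, "none"),
  recA_tus   = list(11.2, 64.1, 21,   16.5, 0.9, NA,   NA,   NA, "dif", FALSE, "rescue"),
  recA_sbcB  = list(12.1, 48.8, 21,   16.7, 4.6, NA,   NA,   NA, "dif", FALSE, "rescue"),
  sbcB_sbcD_recA = list(19.8, 68,  21, 31,   1.2, 11.6, 1,   NA, "dif", FALSE, "rescue"),
  sbcB_sbcD_recB = list(9.8,  27.3, NA, 29.6, 2.2, 5.9, 0.2, NA, "dif", FALSE, "recFOR"),
  ruvAB_recA_recB = list(20.7, 60,  NA, 37.6, 2.2, NA,  NA,  NA, "dif", FALSE, "none"),
  matP_recB  = list(15.5, 86.4, NA,   37.6, 2,   9.2,  1.5,  NA, "dif", FALSE, "none"),
  ftsK_dCter_recB = list(15.8, 82.8, NA, 54.4, 1.2, 15.9, 3.1, NA, "trap", FALSE, "none"),
  matP_ftsK_dCter_recB = list(15.8, 82.8, NA, 39.7, 1.2, NA, NA, NA, "trap", FALSE, "none"),
  # hipA-deleted variant: focus-less cells divide per the measured
  # 0/1/2-division distributions (15/30/5 of 50 first cells; 0/27/4 of 31
  # second cells)
  recB_hipA  = list(17.7, 74.5, NA,   32,   1.5, 7.9,  1,    NA, "dif", TRUE, "none")
)

#' Table of supported genotypes and their measured rates
#'
#' Snapshot focus-less percentages and time-lapse event rates per genotype,
#' as shipped in `inst/extdata/genotype_params.tsv`.
#'
#' @return `data.frame` with one row per genotype.
#' @export
genotype_table <- function() {
  rows <- lapply(names(.genotype_rows), function(g) {
    r <- .genotype_rows[[g]]
    data.frame(genotype = g, initial = r[[1]] / 100,
               transmitted = r[[2]] / 100,
               p_sigma_base = if (is.na(r[[3]])) NA_real_ else r[[3]] / 100,
               snap_ydeV = r[[4]], snap_ydeV_sd = r[[5]],
               snap_yoaC = r[[6]], snap_yoaC_sd = r[[7]],
               snap_ycdN = r[[8]], cleavage = r[[9]],
               focusless_divide = r[[10]], repair_mode = r[[11]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname genotype_table
#' @export
list_genotypes <- function() names(.genotype_rows)

#' Write the genotype parameter table as a versioned TSV
#'
#' Long format: genotype, parameter, value, provenance (measurement type).
#'
#' @param file Output path.
#' @export
write_genotype_table <- function(file) {
  tab <- genotype_table()
  long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    r <- tab[k, ]
    prov <- c(initial = "time-lapse, % of divisions",
              transmitted = "time-lapse, % of initial events",
              p_sigma_base = "time-lapse initial fraction of the Exo V-null double mutant",
              snap_ydeV = "snapshot, % cells with 0 focus (dif-proximal, 10 kb)",
              snap_ydeV_sd = "snapshot sd",
              snap_yoaC = "snapshot, % cells with 0 focus (~300 kb)",
              snap_yoaC_sd = "snapshot sd",
              snap_ycdN = "snapshot, % cells with 0 focus (~500 kb)",
              cleavage = "structural: septum cleavage positioning",
              focusless_divide = "structural: hipAB status",
              repair_mode = "structural: recombination/degradation pathway")
    vals <- vapply(names(prov), function(p) as.character(r[[p]]), "")
    data.frame(genotype = r$genotype, parameter = names(prov),
               value = vals, provenance = unname(prov),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# invert the observed (initial, transmitted) pair to the per-non-carrier
# sigma-formation probability i_eff (see .steady_core)
.calibrate_sigma <- function(initial, transmitted) {
  if (initial == 0) return(0)
  core <- .steady_core(initial, transmitted, input = "initial_fraction")
  core$sigma_rate
}

# degradation scale from the genotype's own snapshot gradient where two or
# more loci were scored; recB's 207 kb otherwise
.calibrate_scale <- function(r, map) {
  d <- c(genome_distance(map, map$loci[["ydeV"]], map$dif_pos),
         genome_distance(map, map$loci[["yoaC"]], map$dif_pos),
         genome_distance(map, map$loci[["ycdN"]], map$dif_pos))
  f <- c(r$snap_ydeV, r$snap_yoaC, r$snap_ycdN) / 100
  keep <- !is.na(f) & f > 0
  if (sum(keep) < 2 || r$initial == 0) {
    recB <- genotype_table()[genotype_table()$genotype == "recB", ]
    return(fit_degradation_scale(d[1:2],
                                 c(recB$snap_ydeV, recB$snap_yoaC) / 100)$scale_kb)
  }
  fit <- fit_degradation_scale(d[keep], f[keep])
  if (!fit$identifiable) 1e4 else fit$scale_kb
}

#' Calibrated stochastic parameters for a genotype
#'
#' Returns the full engine parameter set for one of the supported
#' genotypes. Rates are calibrated from the measured time-lapse statistics
#' by the closed-form branching-process identities (see
#' [implied_event_rates()]):
#' * `p_sigma` - per-cell per-generation probability that replication fork
#'   breakage creates a sigma-replicating chromosome. For `recA`-family
#'   genotypes with active Exo V it is fixed at the Exo V-null double-mutant
#'   baseline (0.21) and `rescue_prob` absorbs the difference.
#' * `repair_prob` - probability the broken fork is repaired by homologous
#'   recombination before division (1 for rec-proficient genotypes,
#'   intermediate for the RecFOR-dependent `sbcB_sbcD_recB`).
#' * `rescue_prob` - probability Exo V degrades the whole linear tail before
#'   division, aborting the event (only nonzero when RecA is absent and
#'   Exo V active).
#' * `continuation_prob` - per-generation probability a carrier repeats the
#'   loss (geometric transmission chain).
#' * `degradation_scale_kb` - mean of the exponential per-end resection
#'   extent, fitted from the genotype's own snapshot loss gradient
#'   (~207 kb for recB, much larger for recA_recD).
#' * `first_division_dist` / `second_division_dist` - division-count
#'   distributions of newly born focus-less cells. Degenerate at zero for
#'   hipAB-intact genotypes (the HipA toxin blocks division of dif-proximal
#'   focus-less cells); the measured 0/1/2-division distributions for the
#'   hipA-deleted variant.
#'
#' @param name Genotype label; see [list_genotypes()].
#' @return Object of class `genotype_params`.
#' @examples
#' p <- default_params("recB")
#' p$continuation_prob            # 0.745
#' round(p$p_sigma, 3)            # calibrated sigma-formation rate
#' @export
default_params <- function(name) {
  if (!name %in% names(.genotype_rows))
    stop("unknown genotype: ", name, "; see list_genotypes()")
  tab <- genotype_table()
  r <- tab[tab$genotype == name, ]
  map <- build_default_genome()
  i_eff <- .calibrate_sigma(r$initial, r$transmitted)
  repair <- 0; rescue <- 0
  if (r$repair_mode == "repair") {
    p_sigma <- 0.18  # the inferred wild-type per-cell fork-breakage rate
    repair <- 1
  } else if (r$repair_mode == "rescue") {
    base <- r$p_sigma_base
    if (i_eff < base) {
      p_sigma <- base
      rescue <- 1 - i_eff / base
    } else p_sigma <- i_eff
  } else if (r$repair_mode == "recFOR") {
    base <- .calibrate_sigma(tab$initial[tab$genotype == "recB"],
                             tab$transmitted[tab$genotype == "recB"])
    p_sigma <- base
    repair <- max(0, 1 - i_eff / base)
  } else {
    p_sigma <- i_eff
  }
  if (r$focusless_divide) {
    first <- c(0.30, 0.60, 0.10)   # 15/30/5 of 50 first focus-less cells
    second <- c(0, 0.87, 0.13)     # 0/27/4 of 31 second focus-less cells
  } else {
    first <- c(1, 0, 0)
    second <- c(1, 0, 0)
  }
  p <- structure(list(
    name = name,
    p_sigma = p_sigma, repair_prob = repair, rescue_prob = rescue,
    continuation_prob = r$transmitted,
    degradation_scale_kb = .calibrate_scale(r, map),
    first_division_dist = first, second_division_dist = second,
    hip_blocked_division = !r$focusless_divide,
    cleavage = r$cleavage,
    dimer_rate = 0.15,
    v_exo_bp_s = 850, v_fork_bp_s = 550,
    target_initial = r$initial, target_transmitted = r$transmitted),
    class = "genotype_params")
  validate_params(p)
  p
}

#' Validate a genotype parameter set
#'
#' Checks the probability-range invariants, that the division distributions
#' sum to one, and that Exo V rescue is only active in RecA-deficient,
#' Exo V-proficient genotypes.
#'
#' @param params A `genotype_params` object.
#' @return `params`, invisibly; errors otherwise.
#' @export
validate_params <- function(params) {
  pr <- c(params$p_sigma, params$repair_prob, params$rescue_prob,
          params$continuation_prob, params$dimer_rate)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  for (d in list(params$first_division_dist, params$second_division_dist))
    if (abs(sum(d) - 1) > 1e-8 || any(d < 0))
      stop("focusless division distributions must sum to 1")
  if (params$degradation_scale_kb < 0) stop("negative degradation scale")
  if (params$rescue_prob > 0 &&
      !grepl("recA", params$name) )
    stop("rescue_prob > 0 requires a recA-deficient genotype")
  invisible(params)
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf("<genotype_params> %s\n", x$name))
  cat(sprintf("  p_sigma %.4f | repair %.2f | rescue %.3f | continuation %.3f\n",
              x$p_sigma, x$repair_prob, x$rescue_prob, x$continuation_prob))
  cat(sprintf("  degradation scale %.0f kb | cleavage at %s | focus-less %s\n",
              x$degradation_scale_kb, x$cleavage,
              if (x$hip_blocked_division) "non-dividing (hipAB+)"
              else "dividing (hipA deleted)"))
  invisible(x)
}
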