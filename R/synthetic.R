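#' Specification of a synthetic fixture
#'
#' Seeded, fully reproducible stand-ins for the study's raw data: a fixture
#' regenerates byte-identically from its spec.
#'
#' @param genotype Genotype label or `genotype_params`.
#' @param topology `"circular"` or `"linear"`.
#' @param n_cells Founding population size.
#' @param n_generations Generations simulated.
#' @param read_depth Total reads for coverage fixtures.
#' @param bin_kb Coverage bin width.
#' @param seed Mandatory integer seed.
#' @return Validated `fixture_spec` list.
#' @export
fixture_spec <- function(genotype, topology = "circular", n_cells = 200,
                         n_generations = 10, read_depth = 1e6, bin_kb = 10,
                         seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory (no silent nondeterminism)")
  if (any(c(n_cells, n_generations, read_depth, bin_kb) <= 0) &&
      n_generations != 0)
    stop("all counts must be positive")
  structure(list(genotype = genotype, topology = topology,
                 n_cells = as.integer(n_cells),
                 n_generations = as.integer(n_generations),
                 read_depth = read_depth, bin_kb = bin_kb,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.spec_sim <- function(spec, record = "all", seed_offset = 0L) {
  run_simulation(sim_config(
    genotype = spec$genotype, topology = spec$topology,
    n_initial = spec$n_cells, n_generations = spec$n_generations,
    seed = spec$seed + seed_offset, record = record))
}

#' Generate a time-lapse division-event table
#'
#' Runs the lineage engine and writes the event-log TSV. Focus loss occurs
#' only at division rows and in exactly one daughter, mirroring the
#' time-lapse observation.
#'
#' @param spec A [fixture_spec()].
#' @param file Output TSV path.
#' @return The simulation, invisibly (the file is the product).
#' @export
make_event_table <- function(spec, file) {
  sim <- .spec_sim(spec, record = "all")
  write_event_log(sim$events, file)
  invisible(sim)
}

#' Generate a per-cell snapshot focus-count table
#'
#' One row per cell with a 0/1/2 focus count per locus.
#'
#' @param spec A [fixture_spec()].
#' @param file Output TSV path.
#' @param growth_exponent,seg_prob Two-focus model knobs (see
#'   [snapshot_stats()]).
#' @return The simulation, invisibly.
#' @export
make_snapshot_table <- function(spec, file, growth_exponent = 1,
                                seg_prob = 0.8) {
  sim <- .spec_sim(spec, record = "none")
  map <- sim$config$map
  pop <- sim$final_population
  out <- data.frame(cell_id = pop$id, stringsAsFactors = FALSE)
  for (loc in names(map$loci)) {
    present <- locus_present(pop, map, loc)
    p2 <- seg_prob *
      (expected_copy_number(map, map$loci[[loc]], growth_exponent) - 1)
    two <- present & (stats::runif(nrow(pop)) < p2)
    out[[paste0("foci_", loc)]] <- ifelse(!present, 0L,
                                          ifelse(two, 2L, 1L))
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sim)
}

#' Generate paired coverage fixtures and their MFA ratio
#'
#' Writes three bedGraph files (`A.bedgraph`, `B.bedgraph`,
#' `ratio.bedgraph`) plus a DCF manifest recording both specs and the
#' package version.
#'
#' @param specA,specB [fixture_spec()]s sharing map and bins
#'   (A = reference).
#' @param dir Output directory (created if needed).
#' @param growth_exponent Replication gradient exponent.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_coverage <- function(specA, specB, dir, growth_exponent = 1) {
  if (specA$bin_kb != specB$bin_kb) stop("bin mismatch")
  if (specA$topology != specB$topology) stop("map mismatch")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  simA <- .spec_sim(specA, record = "none")
  simB <- .spec_sim(specB, record = "none", seed_offset = 1L)
  map <- simA$config$map
  set.seed(specA$seed + 2L)
  mfa <- simulate_mfa(simA$final_population, simB$final_population, map,
                      bin_kb = specA$bin_kb,
                      read_depth = specA$read_depth,
                      growth_exponent = growth_exponent)
  fA <- file.path(dir, "A.bedgraph"); fB <- file.path(dir, "B.bedgraph")
  fR <- file.path(dir, "ratio.bedgraph")
  profA <- attr(mfa, "profileA"); profB <- attr(mfa, "profileB")
  profA$value <- mfa$countA / sum(mfa$countA)
  profB$value <- mfa$countB / sum(mfa$countB)
  write_bedgraph(profA, fA)
  write_bedgraph(profB, fB)
  write_bedgraph(mfa, fR, value = "ratio")
  manifest <- file.path(dir, "MANIFEST.dcf")
  write.dcf(data.frame(
    package = "sigmachrom",
    version = as.character(utils::packageVersion("sigmachrom")),
    genotypeA = if (is.character(specA$genotype)) specA$genotype
                else specA$genotype$name,
    genotypeB = if (is.character(specB$genotype)) specB$genotype
                else specB$genotype$name,
    topology = specA$topology, n_cells = specA$n_cells,
    n_generations = specA$n_generations, read_depth = specA$read_depth,
    bin_kb = specA$bin_kb, seedA = specA$seed, seedB = specB$seed),
    manifest)
  invisible(c(A = fA, B = fB, ratio = fR, manifest = manifest))
}
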