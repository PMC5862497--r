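#' Genome coordinate maps
#'
#' A `genome_map` is the coordinate system every other module works on: a
#' circular (or artificially linearized) chromosome with named loci, the
#' replication origin, the dimer-resolution site *dif*, the *tos*
#' linearization site, the *hipA hipB* toxin-antitoxin operon and the
#' orientation-specific *ter* fork-pause sites that delimit the replication
#' fork trap. All coordinates are continuous kb, 0-based, modulo the genome
#' length on circular maps.
#'
#' @param length_kb Genome length in kb.
#' @param topology `"circular"` or `"linear"`.
#' @param ori_pos,dif_pos,tos_pos,hip_pos Positions (kb) of *oriC*, *dif*,
#'   the *tos* linearization site and the *hipA hipB* operon. `tos_pos` may
#'   be `NA` on maps without the phage N15 system.
#' @param ter_sites `data.frame` with columns `name`, `pos` (kb) and
#'   `blocks` (`"cw"` for sites arresting clockwise forks, `"ccw"` for sites
#'   arresting counter-clockwise forks).
#' @param loci Named numeric vector of locus positions (kb), e.g. the
#'   parS/ParB fluorescent tags.
#' @param linear_break_pos Position of the chromosome interruption for
#'   linear maps; defaults to `tos_pos`.
#'
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(length_kb, topology = c("circular", "linear"),
                       ori_pos, dif_pos, tos_pos = NA_real_, hip_pos,
                       ter_sites, loci = numeric(), linear_break_pos = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.numeric(length_kb), length_kb > 0)
  pos_all <- c(ori_pos, dif_pos, hip_pos, ter_sites$pos, loci)
  if (any(pos_all < 0 | pos_all >= length_kb))
    stop("all positions must lie in [0, length_kb)")
  if (!all(ter_sites$blocks %in% c("cw", "ccw")))
    stop("ter_sites$blocks must be 'cw' or 'ccw'")
  if (topology == "linear") {
    if (is.null(linear_break_pos)) linear_break_pos <- tos_pos
    if (is.na(linear_break_pos))
      stop("linear topology requires linear_break_pos (or tos_pos)")
  } else {
    linear_break_pos <- NA_real_
  }
  map <- structure(
    list(length_kb = length_kb, topology = topology, ori_pos = ori_pos,
         dif_pos = dif_pos, tos_pos = tos_pos, hip_pos = hip_pos,
         ter_sites = ter_sites, loci = loci,
         linear_break_pos = linear_break_pos),
    class = "genome_map")
  trap <- fork_trap_interval(map)
  if (!(dif_pos >= trap[1] && dif_pos <= trap[2]))
    stop("dif_pos must lie inside the replication fork trap")
  map
}

#' Default MG1655-like genome map
#'
#' Builds the 4,641 kb map used throughout: *dif* at 1588 kb, *tos* at
#' 1585 kb, *hipA hipB* at 1588 kb, the parS-tagged loci pspE (1367),
#' yddW (1565), ydeV (1598), gusC (1689), and the approximately placed
#' yoaC (1888, ~300 kb from *dif* on the left replichore) and ycdN (1088,
#' ~500 kb on the right replichore). *ter* sites bracket *dif* in the order
#' terD - terA - dif - terC - terB; their exact positions are not critical
#' and can be overridden by building a custom [genome_map()].
#'
#' @param topology `"circular"` or `"linear"` (linearized at *tos*, 1585 kb).
#' @return A `genome_map`.
#' @examples
#' map <- build_default_genome()
#' genome_distance(map, map$dif_pos, map$loci[["ydeV"]])  # 10 kb
#' @export
build_default_genome <- function(topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  genome_map(
    length_kb = 4641, topology = topology,
    ori_pos = 3926, dif_pos = 1588, tos_pos = 1585, hip_pos = 1588,
    ter_sites = data.frame(
      name = c("terD", "terA", "terC", "terB"),
      pos = c(1280, 1340, 1600, 1680),
      blocks = c("ccw", "ccw", "cw", "cw"),
      stringsAsFactors = FALSE),
    loci = c(ycdN = 1088, pspE = 1367, yddW = 1565, ydeV = 1598,
             gusC = 1689, yoaC = 1888))
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %s, %.0f kb\n", x$topology, x$length_kb))
  cat(sprintf("  ori %.0f | dif %.0f | trap [%.0f, %.0f]\n",
              x$ori_pos, x$dif_pos,
              fork_trap_interval(x)[1], fork_trap_interval(x)[2]))
  cat("  loci:", paste(sprintf("%s=%.0f", names(x$loci), x$loci),
                       collapse = ", "), "\n")
  invisible(x)
}

# position x on the increasing arc from a to b (all mod L)?
.in_arc <- function(x, a, b, L) {
  x <- x %% L; a <- a %% L; b <- b %% L
  ifelse(a <= b, x >= a & x <= b, x >= a | x <= b)
}

.arc_len <- function(a, b, L) (b - a) %% L

#' Distance between two genome positions
#'
#' Circular maps: minimum arc length (always <= length/2). Linear maps: arc
#' length of the unique path that does not cross the linearization point.
#'
#' @param map A [genome_map()].
#' @param a,b Positions in kb (vectorized).
#' @return Distance in kb.
#' @export
genome_distance <- function(map, a, b) {
  L <- map$length_kb
  if (any(c(a, b) < 0 | c(a, b) >= L)) stop("positions out of range")
  if (map$topology == "circular") {
    d <- abs(a - b) %% L
    pmin(d, L - d)
  } else {
    brk <- map$linear_break_pos
    d_ab <- .arc_len(a, b, L)                  # arc a -> b increasing
    crosses <- .in_arc(brk, a, b, L) & !(a == b)
    ifelse(crosses, L - d_ab, d_ab)
  }
}

#' Replication fork trap interval
#'
#' The terminus interval delimited by the outermost oppositely-oriented
#' *ter* sites, within which converging forks meet.
#'
#' @param map A [genome_map()].
#' @return Numeric length-2 vector `c(lo, hi)` in kb.
#' @export
fork_trap_interval <- function(map) {
  ts <- map$ter_sites
  # outermost site on each side of dif
  below <- ts$pos[ts$pos < map$dif_pos]
  above <- ts$pos[ts$pos > map$dif_pos]
  if (!length(below) || !length(above))
    stop("ter sites must bracket dif")
  c(min(below), max(above))
}

#' Is a position inside the replication fork trap?
#'
#' @param map A [genome_map()].
#' @param x Position(s) in kb.
#' @return Logical vector.
#' @export
in_fork_trap <- function(map, x) {
  if (any(x < 0 | x >= map$length_kb)) stop("positions out of range")
  trap <- fork_trap_interval(map)
  x >= trap[1] & x <= trap[2]
}

#' Export / import named loci as 4-column BED
#'
#' Coordinates are converted kb -> bp (x1000), 0-based half-open, on a single
#' sequence named `chr`.
#'
#' @param map A [genome_map()].
#' @param file Path to a BED file.
#' @return `write_loci_bed` returns `file` invisibly; `read_loci_bed`
#'   returns a named numeric vector of kb positions.
#' @export
write_loci_bed <- function(map, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = round(map$loci * 1000) + 1, width = 1),
    name = names(map$loci))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_loci_bed
#' @export
read_loci_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  pos <- (GenomicRanges::start(gr) - 1) / 1000
  names(pos) <- gr$name
  pos
}

#' Serialize a genome map to a structured key/value config file
#'
#' Uses DCF (`key: value`) records; lists of sites are packed as
#' `name=pos` pairs separated by semicolons.
#'
#' @param map A [genome_map()].
#' @param file Path to write/read.
#' @return `read_genome_config` returns a `genome_map`.
#' @export
write_genome_config <- function(map, file) {
  pack <- function(nm, v) paste(sprintf("%s=%g", nm, v), collapse = ";")
  rec <- data.frame(
    length_kb = map$length_kb, topology = map$topology,
    ori_pos = map$ori_pos, dif_pos = map$dif_pos,
    tos_pos = map$tos_pos, hip_pos = map$hip_pos,
    linear_break_pos = map$linear_break_pos,
    ter_sites = pack(map$ter_sites$name, map$ter_sites$pos),
    ter_blocks = paste(map$ter_sites$blocks, collapse = ";"),
    loci = pack(names(map$loci), map$loci))
  write.dcf(rec, file)
  invisible(file)
}

#' @rdname write_genome_config
#' @export
read_genome_config <- function(file) {
  rec <- as.list(as.data.frame(read.dcf(file), stringsAsFactors = FALSE))
  unpack <- function(s) {
    parts <- strsplit(strsplit(s, ";")[[1]], "=")
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                    vapply(parts, `[`, "", 1))
  }
  ter <- unpack(rec$ter_sites)
  genome_map(
    length_kb = as.numeric(rec$length_kb), topology = rec$topology,
    ori_pos = as.numeric(rec$ori_pos), dif_pos = as.numeric(rec$dif_pos),
    tos_pos = as.numeric(rec$tos_pos), hip_pos = as.numeric(rec$hip_pos),
    ter_sites = data.frame(name = names(ter), pos = unname(ter),
                           blocks = strsplit(rec$ter_blocks, ";")[[1]],
                           stringsAsFactors = FALSE),
    loci = unpack(rec$loci),
    linear_break_pos = {
      lb <- as.numeric(rec$linear_break_pos)
      if (is.na(lb)) NULL else lb
    })
}
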