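#' Write a division-event log as TSV
#'
#' Columns: generation, parent_id, classification, cleavage_pos_kb, chain,
#' followup, lost_loci (semicolon-joined locus names absent from the
#' focus-less daughter at birth).
#'
#' @param events Event `data.frame` (from [run_simulation()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_event_log <- function(events, file) {
  utils::write.table(events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(lost_loci = "character"))
}

#' Write a population snapshot as TSV
#'
#' One row per cell: cell_id, topology_state, carrier, viable, and one
#' presence flag per locus of the map.
#'
#' @param pop Population `data.frame`.
#' @param map A [genome_map()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_population_snapshot <- function(pop, map, file) {
  out <- data.frame(cell_id = pop$id, topology_state = pop$state,
                    carrier = pop$carrier, viable = pop$viable,
                    stringsAsFactors = FALSE)
  for (loc in names(map$loci))
    out[[paste0("has_", loc)]] <- as.integer(locus_present(pop, map, loc))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Export a coverage or ratio profile as bedGraph
#'
#' Positions are converted kb -> bp on a single sequence named `chr`.
#'
#' @param profile A `coverage_profile`, or any `data.frame` with
#'   `start_kb`, `end_kb` and a value column.
#' @param file Output path.
#' @param value Name of the value column (default `"value"`, or
#'   `"ratio"` if present and `value` is absent).
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(profile, file, value = NULL) {
  if (is.null(value))
    value <- if ("value" %in% names(profile)) "value" else "ratio"
  v <- profile[[value]]
  keep <- is.finite(v)
  gr <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(
      start = round(profile$start_kb[keep] * 1000) + 1,
      end = round(profile$end_kb[keep] * 1000)),
    score = v[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  data.frame(start_kb = (GenomicRanges::start(gr) - 1) / 1000,
             end_kb = GenomicRanges::end(gr) / 1000,
             value = gr$score)
}
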