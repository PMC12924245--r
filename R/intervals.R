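# Genomic intervals are plain data.frames with columns
# genome_id, start, end, strand -- 0-based half-open internally.
# All human-facing output is 1-based inclusive (see write_regions()).

#' Construct a genomic interval table
#'
#' Internal coordinates are 0-based half-open: a feature covering the first
#' ten bases of a genome is `[0, 10)`. Conversions to and from the 1-based
#' inclusive convention used by GFF3/GenBank and in reports are handled by
#' [to_1based()] and [from_1based()].
#'
#' @param genome_id Character vector of genome identifiers.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param genome_length Optional genome length(s); when given, `end` must not
#'   exceed it.
#' @return A data.frame with columns genome_id, start, end, strand.
#' @export
genomic_interval <- function(genome_id, start, end, strand = ".",
                             genome_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  n <- max(length(genome_id), length(start), length(end), length(strand))
  gi <- data.frame(genome_id = rep_len(as.character(genome_id), n),
                   start = rep_len(start, n),
                   end = rep_len(end, n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (any(gi$start < 0L)) stop("interval start must be >= 0")
  if (any(gi$start >= gi$end)) stop("interval requires start < end")
  if (!all(gi$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  if (!is.null(genome_length) && any(gi$end > rep_len(genome_length, n))) {
    stop("interval end exceeds genome length")
  }
  gi
}

#' Convert internal 0-based half-open coordinates to 1-based inclusive
#' @param df Data.frame with `start` and `end` columns (0-based half-open).
#' @return The same data.frame with `start_1based`/`end_1based` added.
#' @export
to_1based <- function(df) {
  df$start_1based <- df$start + 1L
  df$end_1based <- df$end
  df
}

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#' @param start_1based,end_1based Integer vectors, 1-based inclusive.
#' @return List with `start` and `end` in internal convention.
#' @export
from_1based <- function(start_1based, end_1based) {
  list(start = as.integer(start_1based) - 1L, end = as.integer(end_1based))
}

#' Region length in kb as printed in reports
#'
#' `(end - start) / 1000`, rounded half-up to one decimal, matching the
#' presentation of region lengths in per-prophage summary tables.
#' @param start,end Internal 0-based half-open coordinates.
#' @return Numeric vector of lengths in kb with one decimal.
#' @export
length_kb <- function(start, end) {
  floor((end - start) / 100 + 0.5) / 10
}

# IRanges helpers: internal [start, end) maps to IRanges [start+1, end].
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}
iranges_to_df <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
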