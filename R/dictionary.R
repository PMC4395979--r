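#' Build per-ROA word dictionaries from read segments
#'
#' A word is a unique ROA-length segment sequence observed in an ROA.  The
#' dictionary compresses all read data of an ROA into the set of words with
#' their per-strand occurrence counts; per-strand coverage of the ROA is the
#' total number of segments, so counts are conserved exactly.
#'
#' @param segments Segment table from [assign_reads()].
#' @return A list of class `roa_dictionaries` with elements
#'   \describe{
#'     \item{words}{data.table: `track`, `roa_start`, `bases`, `plus`, `minus`}
#'     \item{coverage}{data.table: `track`, `roa_start`, `plus_cov`, `minus_cov`}
#'   }
#' @export
build_dictionaries <- function(segments) {
  dt <- data.table::as.data.table(segments)
  if (nrow(dt) == 0L) {
    words <- data.table::data.table(track = character(), roa_start = integer(),
                                    bases = character(), plus = integer(),
                                    minus = integer())
    cov <- data.table::data.table(track = character(), roa_start = integer(),
                                  plus_cov = integer(), minus_cov = integer())
    return(structure(list(words = words, coverage = cov),
                     class = "roa_dictionaries"))
  }
  plus <- minus <- track <- roa_start <- bases <- NULL # R CMD check NSE
  words <- dt[, list(plus = sum(strand == "+"), minus = sum(strand == "-")),
              by = list(track, roa_start, bases)]
  cov <- words[, list(plus_cov = sum(plus), minus_cov = sum(minus)),
               by = list(track, roa_start)]
  data.table::setkey(words, track, roa_start)
  structure(list(words = words, coverage = cov), class = "roa_dictionaries")
}

#' Threshold parameters for bidirectional word filtering
#'
#' The retention threshold is coverage dependent: in each strand direction a
#' word must reach `max(absolute_min, ceiling(ppm * 1e-6 * strand_coverage))`
#' occurrences.  The relative part (parts per million of per-strand ROA
#' coverage) governs at high coverage, the absolute minimum at low coverage.
#' Two roles are conventional: a stringent setting (default 750 ppm) while
#' generating alternate reference fragments during iteration, and a more
#' permissive setting (default 400 ppm) for final variant discovery.
#'
#' @param ppm Relative threshold in parts per million of per-strand coverage.
#' @param absolute_min Absolute per-strand minimum count (>= 1).
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(ppm = 750, absolute_min = 2L) {
  stopifnot(ppm > 0, absolute_min >= 1)
  structure(list(ppm = ppm, absolute_min = as.integer(absolute_min)),
            class = "threshold_params")
}

#' Apply the bidirectional threshold filter to dictionaries
#'
#' Retains only words observed on both strands at or above the
#' coverage-dependent per-strand threshold.  Words seen on a single strand
#' are always rejected (strand bias is the signature of process error).
#'
#' @param dictionaries An `roa_dictionaries` object.
#' @param params A [threshold_params()] object.
#' @return An `roa_dictionaries` object whose `words` table is the retained
#'   subset (coverage statistics are unchanged: coverage is a property of the
#'   data, not of the filter).
#' @export
threshold_words <- function(dictionaries, params) {
  words <- dictionaries$words
  cov <- dictionaries$coverage
  if (nrow(words) == 0L) return(dictionaries)
  plus_cov <- minus_cov <- plus <- minus <- NULL
  m <- cov[words, on = c("track", "roa_start")]
  t_plus <- pmax(params$absolute_min, ceiling(params$ppm * 1e-6 * m$plus_cov))
  t_minus <- pmax(params$absolute_min, ceiling(params$ppm * 1e-6 * m$minus_cov))
  keep <- m$plus >= t_plus & m$minus >= t_minus
  structure(list(words = words[keep], coverage = cov),
            class = "roa_dictionaries")
}

#' Does a single word pass the bidirectional threshold?
#'
#' Scalar form of [threshold_words()] for inspection and testing.
#'
#' @param plus_count,minus_count Per-strand counts of the word.
#' @param plus_cov,minus_cov Per-strand ROA coverage.
#' @param params A [threshold_params()] object.
#' @return Logical.
#' @export
passes_threshold <- function(plus_count, minus_count, plus_cov, minus_cov,
                             params) {
  t_plus <- max(params$absolute_min, ceiling(params$ppm * 1e-6 * plus_cov))
  t_minus <- max(params$absolute_min, ceiling(params$ppm * 1e-6 * minus_cov))
  plus_count >= t_plus && minus_count >= t_minus
}
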