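#' One-shot ROA analysis of mapped reads
#'
#' Runs the core analysis on a single mapping (no iteration): assign reads
#' to ROAs, build dictionaries, filter at the final threshold, cross-verify,
#' tally positions and call variants.  Accepts either a read table (e.g. a
#' simulator truth alignment) or a SAM/BAM path.
#'
#' @param reads Read table (`qname`, `rname`, `pos` 0-based, `cigar`,
#'   `strand`, `seq`) or a SAM/BAM file path.
#' @param reference Named character vector with one primary reference.
#' @param roa_length,offset ROA geometry.
#' @param params Final [threshold_params()] (default 400 ppm).
#' @param accept_prop Fragment acceptance share (see [assemble_fragments()]).
#' @param min_vaf,min_count Variant-call thresholds.
#' @param eligibility Verification statuses eligible for calling.
#' @return List of class `roa_analysis`: `collection`, `raw_dictionaries`,
#'   `dictionaries` (thresholded + verified), `tally`, `coverage`,
#'   `variants`, `fragments`.
#' @export
analyze_reads <- function(reads, reference, roa_length = 34L, offset = 0L,
                          params = threshold_params(400, 2L),
                          accept_prop = 0.02, min_vaf = 0, min_count = 1L,
                          eligibility = "full") {
  stopifnot(length(reference) == 1L, !is.null(names(reference)))
  ref_name <- names(reference)[1]
  ref_seq <- unname(reference[1])
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_alignments(reads, reference_names = ref_name)
  collection <- roa_collection(ref_name, nchar(ref_seq), roa_length, offset)
  segs <- assign_reads(reads, collection)
  raw <- build_dictionaries(segs)
  dicts <- verify_words(threshold_words(raw, params), collection)
  tally <- tally_positions(dicts, collection, eligibility = eligibility)
  variants <- call_variants(tally, ref_seq, min_vaf = min_vaf,
                            min_count = min_count)
  fragments <- assemble_fragments(dicts, collection, ref_seq,
                                  accept_prop = accept_prop)
  structure(list(collection = collection, raw_dictionaries = raw,
                 dictionaries = dicts, tally = tally$tally,
                 coverage = tally$coverage, variants = variants,
                 fragments = fragments),
            class = "roa_analysis")
}

#' @export
print.roa_analysis <- function(x, ...) {
  cat(sprintf("ROA analysis of '%s': %d word(s) retained, %d variant call(s), %d fragment(s)\n",
              x$collection$reference_name, nrow(x$dictionaries$words),
              nrow(x$variants), nrow(x$fragments)))
  invisible(x)
}
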