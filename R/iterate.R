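#' Lift fragment-mapped reads to primary coordinates and deduplicate
#'
#' Reads mapped to an allele fragment are lifted to the primary reference by
#' adding the fragment's anchor offset (fragments are gap-free, so the lift
#' is a pure offset).  A read mapped to several references is counted once:
#' the alignment with the fewest mismatches wins, ties preferring the
#' primary reference.
#'
#' @param mapped Mapped-read table (from [map_reads_kmer()] or a
#'   [mapper_adapter()]), possibly with one read on several references.
#' @param refset The [reference_set()] that was mapped against.
#' @return Read table in primary coordinates, one row per read, suitable for
#'   [assign_reads()].
#' @export
aggregate_to_reference <- function(mapped, refset) {
  if (nrow(mapped) == 0L) return(mapped)
  m <- data.table::copy(mapped)
  ri <- match(m$rname, refset$name)
  if (anyNA(ri)) stop("mapped reads reference unknown sequences")
  frag <- !refset$is_primary[ri]
  if (any(frag & is.na(refset$anchor[ri])))
    stop("fragment without anchor in reference set")
  m$pos[frag] <- m$pos[frag] + refset$anchor[ri][frag]
  m$rname[frag] <- refset$anchor_ref[ri][frag]
  data.table::setorder(m, qname, nm, -is_primary, rname, pos)
  m[!duplicated(m$qname)]
}

#' Iterative remapping against a fragment-enriched reference set
#'
#' Runs the loop: map all reads against the current reference set, assign to
#' ROAs, build dictionaries, filter at the stringent iterative threshold,
#' cross-verify, assemble alternate reference fragments, enrich the
#' reference set, and remap -- until the set of iterative-threshold-passing
#' words (in primary reference coordinates) stops changing, or `max_iter` is
#' reached.  Fragments are accumulated, never retired.  After convergence
#' the final mapping is re-analyzed at the permissive final threshold,
#' verified, and tallied into variant calls.
#'
#' @param reads data.table with `qname`, `seq` (sequencing orientation).
#' @param reference Named character vector with one primary reference.
#' @param roa_length,offset ROA geometry (see [roa_collection()]).
#' @param iter_params Stringent [threshold_params()] used while generating
#'   fragments (default 750 ppm).
#' @param final_params Permissive [threshold_params()] used for final
#'   variant discovery (default 400 ppm).
#' @param accept_prop Fragment acceptance share for non-fully-verified
#'   words (see [assemble_fragments()]).
#' @param max_iter Hard iteration cap (default 10).
#' @param mapper `NULL` for the built-in k-mer mapper, a
#'   [mapper_adapter()], or a list of mappers alternated across iterations.
#' @param k,max_mismatch,min_overlap Built-in mapper settings.
#' @param min_vaf,min_count Final variant-call thresholds.
#' @param eligibility Verification statuses eligible for calling
#'   (see [tally_positions()]).
#' @return List of class `iteration_result`: `iterations`, `converged`,
#'   `history` (per-iteration mapped/word/fragment counts), `fragments`,
#'   `dictionaries` (final verified), `tally`, `variants`, `mapped_reads`,
#'   `collection`.
#' @export
iterate_mapping <- function(reads, reference, roa_length = 34L, offset = 0L,
                            iter_params = threshold_params(750, 2L),
                            final_params = threshold_params(400, 2L),
                            accept_prop = 0.02, max_iter = 10L, mapper = NULL,
                            k = 12L, max_mismatch = 2L, min_overlap = 50L,
                            min_vaf = 0, min_count = 1L,
                            eligibility = "full") {
  stopifnot(length(reference) == 1L, !is.null(names(reference)))
  ref_name <- names(reference)[1]
  ref_seq <- unname(reference[1])
  collection <- roa_collection(ref_name, nchar(ref_seq), roa_length, offset)
  mappers <- if (is.null(mapper)) NULL else
    if (is.list(mapper)) mapper else list(mapper)

  fragments <- NULL
  prev_words <- NULL
  history <- list()
  converged <- FALSE
  it <- 0L
  lifted <- NULL
  dicts <- NULL
  while (it < max_iter) {
    it <- it + 1L
    refset <- reference_set(reference, fragments, ref_name)
    mapped <- if (is.null(mappers)) {
      map_reads_kmer(reads, refset, k = k, max_mismatch = max_mismatch,
                     min_overlap = min_overlap)
    } else {
      mappers[[(it - 1L) %% length(mappers) + 1L]](reads, refset)
    }
    lifted <- aggregate_to_reference(mapped, refset)
    segs <- assign_reads(lifted, collection)
    dicts <- build_dictionaries(segs)
    iterd <- threshold_words(dicts, iter_params)
    wset <- paste(iterd$words$track, iterd$words$roa_start, iterd$words$bases)
    verified <- verify_words(iterd, collection)
    frags_new <- assemble_fragments(verified, collection, ref_seq,
                                    accept_prop = accept_prop)
    n_before <- if (is.null(fragments)) 0L else nrow(fragments)
    fragments <- if (is.null(fragments)) frags_new else
      rbind(fragments, frags_new)[!duplicated(seq)]
    history[[it]] <- data.table::data.table(
      iteration = it, mapped = nrow(lifted), words = length(wset),
      fragments = nrow(fragments))
    if ((!is.null(prev_words) && setequal(wset, prev_words)) ||
        nrow(fragments) == n_before) {
      converged <- TRUE
      break
    }
    prev_words <- wset
  }

  finald <- verify_words(threshold_words(dicts, final_params), collection)
  tally <- tally_positions(finald, collection, eligibility = eligibility)
  variants <- call_variants(tally, ref_seq, min_vaf = min_vaf,
                            min_count = min_count)
  structure(list(iterations = it, converged = converged,
                 history = data.table::rbindlist(history),
                 fragments = fragments, dictionaries = finald,
                 tally = tally, variants = variants, mapped_reads = lifted,
                 collection = collection),
            class = "iteration_result")
}

#' @export
print.iteration_result <- function(x, ...) {
  cat(sprintf("iterative remapping: %d iteration(s), %s\n", x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$history)
  cat(sprintf("%d fragment(s), %d variant call(s)\n",
              if (is.null(x$fragments)) 0L else nrow(x$fragments),
              nrow(x$variants)))
  invisible(x)
}
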