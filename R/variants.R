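#' Tally verified words at each reference position
#'
#' Every eligible word contributes its per-strand count total to its base at
#' each of the positions it spans.  A position inside the analyzed span is
#' covered by one ROA of each track, and because a read feeds exactly one
#' track, summing both tracks' words counts each read once.  `-` symbols
#' (deletions) and `N` contribute to separate tallies, never to a base call;
#' position coverage is the total contribution of all eligible words, so base
#' counts plus the deletion and N tallies conserve coverage exactly.
#'
#' @param dictionaries Verified `roa_dictionaries` (final, permissive
#'   threshold).
#' @param collection The [roa_collection()].
#' @param eligibility Which verification statuses contribute:
#'   `"full"` (default; fully verified words only), `"partial"` (fully plus
#'   partially verified -- useful at span ends, which can never be fully
#'   verified), or `"all"` (no verification requirement).
#' @return List with `tally` (data.table `pos` 0-based, `base`, `count`) and
#'   `coverage` (data.table `pos`, `coverage`).
#' @export
tally_positions <- function(dictionaries, collection,
                            eligibility = c("full", "partial", "all")) {
  eligibility <- match.arg(eligibility)
  w <- dictionaries$words
  L <- collection$roa_length
  empty <- list(tally = data.table::data.table(pos = integer(),
                                               base = character(),
                                               count = integer()),
                coverage = data.table::data.table(pos = integer(),
                                                  coverage = integer()))
  if (nrow(w) == 0L) return(empty)
  if (eligibility != "all") {
    if (!"status" %in% names(w))
      stop("run verify_words() first, or use eligibility = 'all'")
    keep <- switch(eligibility,
                   full = w$status == "fully_verified",
                   partial = w$status != "unverified")
    w <- w[keep]
  }
  if (nrow(w) == 0L) return(empty)
  n <- nrow(w)
  idx <- rep.int(seq_len(n), L)
  off <- rep(0:(L - 1L), each = n)
  pos <- w$roa_start[idx] + off
  base <- substring(w$bases[idx], off + 1L, off + 1L)
  count <- w$plus[idx] + w$minus[idx]
  long <- data.table::data.table(pos = pos, base = base, count = count)
  tal <- long[, list(count = sum(count)), by = list(pos, base)]
  cov <- tal[, list(coverage = sum(count)), by = list(pos)]
  data.table::setkey(tal, pos, base)
  list(tally = tal, coverage = cov)
}

#' Call single-nucleotide variants from a position tally
#'
#' Reports every (position, alternate base) whose supporting count and
#' frequency clear the thresholds.  Multiple alternate bases at one position
#' are each reported -- sites where independent subclones mutate the same
#' base differently are real and common in hypermutated regions, unlike the
#' single-call-per-site convention of pileup-based callers.  The reference
#' base is always taken from the primary reference.  Deletion tallies are
#' not emitted as SNVs.
#'
#' @param tally Output of [tally_positions()].
#' @param reference Primary reference sequence string.
#' @param min_vaf Minimum variant allele frequency (default 0).
#' @param min_count Minimum supporting read count (default 1; words have
#'   already passed the bidirectional threshold filter).
#' @return data.table with `pos` (0-based), `ref`, `alt`, `count`,
#'   `coverage`, `frequency`, ordered by position.
#' @export
call_variants <- function(tally, reference, min_vaf = 0, min_count = 1L) {
  tal <- tally$tally
  cov <- tally$coverage
  if (nrow(tal) == 0L)
    return(data.table::data.table(pos = integer(), ref = character(),
                                  alt = character(), count = integer(),
                                  coverage = integer(), frequency = numeric()))
  m <- cov[tal, on = "pos"]
  refb <- substring(reference, m$pos + 1L, m$pos + 1L)
  keep <- m$base %in% c("A", "C", "G", "T") & m$base != refb &
    m$count >= min_count & m$count / m$coverage >= min_vaf
  out <- data.table::data.table(pos = m$pos[keep], ref = refb[keep],
                                alt = m$base[keep], count = m$count[keep],
                                coverage = m$coverage[keep])
  out$frequency <- out$count / out$coverage
  data.table::setorder(out, pos, alt)
  out
}
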