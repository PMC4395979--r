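#' Cross-verify dictionary words by half-word matching
#'
#' A word covering reference interval `[s, s+L)` is split into halves.  Its
#' left half occupies the same genomic interval as the right half of any word
#' in the other track's ROA starting at `s - L/2`; its right half likewise
#' pairs with the left halves of the other track's ROA starting at `s + L/2`.
#' Because every read feeds exactly one track, those overlapping dictionaries
#' are built from independent read sets, so an exact half-sequence match is
#' independent replication of every variant the half carries.  Words matching
#' on both sides are `fully_verified`, on one side `partially_verified_left`
#' or `partially_verified_right`, else `unverified`.  Halves containing `N`
#' or `-` never match.  Boundary ROAs that lack one overlapping ROA can at
#' best be partially verified on the existing side.
#'
#' @param dictionaries Threshold-filtered `roa_dictionaries`
#'   (verification is only meaningful between threshold-passing words).
#' @param collection The [roa_collection()] the dictionaries were built on.
#' @return The `roa_dictionaries` object with a `status` column added to
#'   `words`.
#' @export
verify_words <- function(dictionaries, collection) {
  words <- data.table::copy(dictionaries$words)
  L <- collection$roa_length
  half <- L %/% 2L
  if (nrow(words) == 0L) {
    words$status <- character(0)
    return(structure(list(words = words, coverage = dictionaries$coverage),
                     class = "roa_dictionaries"))
  }
  lh <- substr(words$bases, 1L, half)
  rh <- substr(words$bases, half + 1L, L)
  ok_l <- !grepl("[N-]", lh)
  ok_r <- !grepl("[N-]", rh)
  other <- ifelse(words$track == "A", "B", "A")
  # verifier keys: track|roa_start|half-string
  key_rh <- paste(words$track, words$roa_start, rh)[ok_r]
  key_lh <- paste(words$track, words$roa_start, lh)[ok_l]
  left_match <- ok_l & paste(other, words$roa_start - half, lh) %in% key_rh
  right_match <- ok_r & paste(other, words$roa_start + half, rh) %in% key_lh
  words$status <- ifelse(left_match & right_match, "fully_verified",
                  ifelse(left_match, "partially_verified_left",
                  ifelse(right_match, "partially_verified_right",
                         "unverified")))
  structure(list(words = words, coverage = dictionaries$coverage),
            class = "roa_dictionaries")
}

ref_window <- function(reference, start0, end0) {
  # clamped 0-based half-open window of the reference string
  n <- nchar(reference)
  substr(reference, max(0L, start0) + 1L, min(n, end0))
}

#' Assemble alternate reference allele fragments from verified words
#'
#' Each retained word is extended by half an ROA on both sides into a
#' fragment of twice the ROA length, anchored at reference coordinates, for
#' use as an additional reference sequence in remapping.  Fully verified
#' words are extended with every combination of matching verifier words from
#' the two overlapping ROAs (one fragment per left x right combination).
#' Partially verified words are extended with verifier words on their
#' verified side and with reference sequence on the other; unverified words
#' with reference sequence on both sides.  Non-fully-verified words spawn
#' fragments only when the central word accounts for at least `accept_prop`
#' of its ROA coverage.  Words containing `N` or `-` are excluded (fragments
#' must be plain DNA for a mapper); duplicate fragment sequences are emitted
#' once; fragments identical to the corresponding reference window are
#' suppressed.  At the ends of the analyzed span fragments are truncated to
#' the available reference.
#'
#' @param dictionaries Verified `roa_dictionaries` (from [verify_words()]).
#' @param collection The [roa_collection()].
#' @param reference Reference sequence string.
#' @param accept_prop Minimum coverage share of a non-fully-verified central
#'   word (default 0.02; this must sit above the coverage share of noise
#'   words surviving the iterative threshold, while admitting subclone words
#'   whose apparent share is attenuated by the mapping failure that
#'   iteration is meant to repair).
#' @return data.table with columns `seq`, `anchor` (0-based reference start),
#'   `central_track`, `central_start`, `status`.
#' @export
assemble_fragments <- function(dictionaries, collection, reference,
                               accept_prop = 0.02) {
  words <- dictionaries$words
  cov <- dictionaries$coverage
  L <- collection$roa_length
  half <- L %/% 2L
  empty <- data.table::data.table(seq = character(), anchor = integer(),
                                  central_track = character(),
                                  central_start = integer(),
                                  status = character())
  if (nrow(words) == 0L) return(empty)
  if (!"status" %in% names(words))
    stop("run verify_words() before assemble_fragments()")
  w <- data.table::copy(words)
  w <- w[!grepl("[N-]", w$bases)]
  if (nrow(w) == 0L) return(empty)
  w$lh <- substr(w$bases, 1L, half)
  w$rh <- substr(w$bases, half + 1L, L)
  w$other <- ifelse(w$track == "A", "B", "A")

  m <- cov[w, on = c("track", "roa_start")]
  share <- (m$plus + m$minus) / (m$plus_cov + m$minus_cov)
  w <- w[w$status == "fully_verified" | share >= accept_prop]
  if (nrow(w) == 0L) return(empty)

  # verifier tables keyed by (track, roa_start, matching half)
  verif <- data.table::copy(words)
  verif$lh <- substr(verif$bases, 1L, half)
  verif$rh <- substr(verif$bases, half + 1L, L)
  vleft <- verif[!grepl("[N-]", verif$rh),
                 list(vtrack = track, vstart = roa_start, match = rh,
                      ext = lh)]
  vright <- verif[!grepl("[N-]", verif$lh),
                  list(vtrack = track, vstart = roa_start, match = lh,
                       ext = rh)]

  pieces <- lapply(seq_len(nrow(w)), function(i) {
    s <- w$roa_start[i]
    st <- w$status[i]
    left_ref <- ref_window(reference, s - half, s)
    right_ref <- ref_window(reference, s + L, s + L + half)
    lefts <- if (st %in% c("fully_verified", "partially_verified_left")) {
      vleft$ext[vleft$vtrack == w$other[i] & vleft$vstart == s - half &
                vleft$match == w$lh[i]]
    } else character(0)
    rights <- if (st %in% c("fully_verified", "partially_verified_right")) {
      vright$ext[vright$vtrack == w$other[i] & vright$vstart == s + half &
                 vright$match == w$rh[i]]
    } else character(0)
    if (length(lefts) == 0L) lefts <- left_ref
    if (length(rights) == 0L) rights <- right_ref
    combo <- expand.grid(l = lefts, r = rights, stringsAsFactors = FALSE)
    anchor <- max(0L, s - half)
    data.table::data.table(
      seq = paste0(combo$l, w$bases[i], combo$r),
      anchor = anchor, central_track = w$track[i], central_start = s,
      status = st)
  })
  frags <- data.table::rbindlist(pieces)
  # suppress reference-identical fragments, dedup sequences
  refwin <- vapply(seq_len(nrow(frags)), function(i)
    ref_window(reference, frags$anchor[i], frags$anchor[i] + nchar(frags$seq[i])),
    character(1))
  frags <- frags[frags$seq != refwin]
  frags[!duplicated(frags$seq)]
}
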