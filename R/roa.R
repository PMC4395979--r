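#' Partition a reference into two offset tracks of regions of analysis
#'
#' A region of analysis (ROA) is a fixed, even-length window of the reference.
#' An ROA collection holds two tracks of abutting ROAs: track A starts at
#' `offset`, track B is shifted by half an ROA length, so every interior
#' position is covered by exactly one ROA of each track and the two ROAs
#' covering a position overlap by half their length.  Reads are later assigned
#' to exactly one track, which makes the two dictionaries covering any
#' position independent read sets -- the basis of cross-verification.
#'
#' No partial ROAs are created: reference sequence beyond the last full
#' window is not analyzed.
#'
#' @param reference_name Name of the reference sequence.
#' @param reference_length Length of the reference in bases.
#' @param roa_length Even ROA length in bases (default 34).
#' @param offset 0-based analysis start position on the reference (default 0).
#' @return An object of class `roa_collection`: a list with the track A and
#'   track B ROA start vectors (0-based), the ROA length and the offset.
#' @examples
#' col <- roa_collection("ref", 102, roa_length = 34)
#' col$track_a  # 0, 34, 68
#' col$track_b  # 17, 51
#' @export
roa_collection <- function(reference_name, reference_length, roa_length = 34L,
                           offset = 0L) {
  roa_length <- as.integer(roa_length)
  offset <- as.integer(offset)
  if (roa_length %% 2L != 0L || roa_length < 8L)
    stop("roa_length must be an even integer >= 8")
  if (reference_length < offset + 2L * roa_length)
    stop("reference too short: need at least 2 x roa_length past the offset")
  half <- roa_length %/% 2L
  track_a <- seq.int(offset, reference_length - roa_length, by = roa_length)
  b0 <- offset + half
  track_b <- if (b0 + roa_length <= reference_length)
    seq.int(b0, reference_length - roa_length, by = roa_length) else integer(0)
  structure(list(reference_name = reference_name,
                 reference_length = as.integer(reference_length),
                 roa_length = roa_length, offset = offset,
                 track_a = as.integer(track_a), track_b = as.integer(track_b)),
            class = "roa_collection")
}

#' @export
print.roa_collection <- function(x, ...) {
  cat(sprintf("ROA collection on '%s' (%d bp): roa_length=%d, offset=%d\n",
              x$reference_name, x$reference_length, x$roa_length, x$offset))
  cat(sprintf("  track A: %d ROAs starting at %d; track B: %d ROAs starting at %d\n",
              length(x$track_a), x$track_a[1], length(x$track_b),
              if (length(x$track_b)) x$track_b[1] else NA_integer_))
  invisible(x)
}

# --- CIGAR arithmetic ---------------------------------------------------------

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(op = ops, len = lens)
}

#' Reference positions consumed by a CIGAR string
#'
#' M, =, X, D and N consume reference; I, S and H do not.  Because these ops
#' are contiguous on the reference the footprint is a single half-open
#' interval `[start, start + ref_width)`.
#'
#' @param start 0-based leftmost mapped position.
#' @param cigar CIGAR string.
#' @return Integer vector `c(start, end)` of the half-open footprint.
#' @export
reference_footprint <- function(start, cigar) {
  co <- cigar_ops(cigar)
  w <- sum(co$len[co$op %in% c("M", "=", "X", "D", "N")])
  c(as.integer(start), as.integer(start) + w)
}

query_width <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "=", "X", "I", "S")])
}

# Render the read as a reference-aligned string starting at `pos`: aligned
# bases for M/=/X, '-' for each deleted/skipped reference base, inserted and
# soft-clipped bases dropped.  Insertions are tallied by the caller.
aligned_string <- function(seq, cigar) {
  co <- cigar_ops(cigar)
  out <- character(length(co$op))
  qi <- 1L
  for (i in seq_along(co$op)) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "=", "X")) {
      out[i] <- substr(seq, qi, qi + len - 1L); qi <- qi + len
    } else if (op %in% c("D", "N")) {
      out[i] <- strrep("-", len)
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } # H, P: nothing
  }
  paste0(out, collapse = "")
}

is_simple_cigar <- function(cigar) grepl("^[0-9]+M$", cigar)

# Soft-clip-flanked match: `aS bM cS` -> drop clips, keep match block.
simple_clip <- function(cigar) {
  m <- regmatches(cigar, regexec("^(?:([0-9]+)S)?([0-9]+)M(?:([0-9]+)S)?$", cigar))[[1]]
  if (length(m) == 0L) return(NULL)
  c(left = ifelse(m[2] == "", 0L, as.integer(m[2])), m = as.integer(m[3]))
}

#' Assign mapped reads to ROAs and extract ROA-sized read segments
#'
#' Each read is assigned to exactly one ROA track.  Candidate ROAs are those
#' fully contained in the read's reference footprint; the chosen ROA is the
#' candidate whose start is nearest the read's 5' end in read orientation
#' (plus strand: smallest start; minus strand: largest end; tie between the
#' tracks goes to track A).  If the footprint fully contains further abutting
#' ROAs of the chosen track the read is split into one segment per contained
#' same-track ROA.  Segment bases are the aligned bases over the ROA with
#' insertions dropped and deletions rendered as `-`.  Reads covering no full
#' ROA yield no segments.
#'
#' @param reads A data.frame of mapped reads with columns `qname`, `rname`,
#'   `pos` (0-based leftmost), `cigar`, `strand` (`"+"`/`"-"`), `seq`.
#' @param collection An [roa_collection()] for `rname`.
#' @return A data.table of segments with columns `qname`, `track` ("A"/"B"),
#'   `roa_start` (0-based), `bases` (length `roa_length`), `strand`.
#' @export
assign_reads <- function(reads, collection) {
  L <- collection$roa_length
  half <- L %/% 2L
  off <- collection$offset
  n <- nrow(reads)
  if (n == 0L)
    return(data.table::data.table(qname = character(), track = character(),
                                  roa_start = integer(), bases = character(),
                                  strand = character()))
  pos <- as.integer(reads$pos)
  seq <- as.character(reads$seq)
  cigar <- as.character(reads$cigar)
  strand <- as.character(reads$strand)

  # Reduce every read to (footprint start, reference-aligned string).
  simple <- is_simple_cigar(cigar)
  astr <- character(n)
  apos <- pos
  astr[simple] <- seq[simple]
  if (any(!simple)) {
    for (i in which(!simple)) {
      sc <- simple_clip(cigar[i])
      if (!is.null(sc)) {
        astr[i] <- substr(seq[i], sc["left"] + 1L, sc["left"] + sc["m"])
      } else {
        astr[i] <- aligned_string(seq[i], cigar[i])
      }
    }
  }
  fs <- apos
  fe <- apos + nchar(astr)

  # First fully-contained ROA start per track, and number contained
  # (clamped to ROAs that actually exist in the collection).
  first_in <- function(track_off) {
    k <- ceiling((fs - track_off) / L)
    pmax(track_off, track_off + as.integer(k) * L)
  }
  a1 <- first_in(off)
  b1 <- first_in(off + half)
  a_end_max <- max(collection$track_a) + L
  b_end_max <- if (length(collection$track_b)) max(collection$track_b) + L else -1L
  na <- pmax(0L, as.integer((pmin(fe, a_end_max) - a1) %/% L))
  nb <- pmax(0L, as.integer((pmin(fe, b_end_max) - b1) %/% L))
  # na/nb: number of same-track ROAs fully inside the footprint
  has_a <- na > 0L
  has_b <- nb > 0L

  plus <- strand == "+"
  a_last_end <- a1 + na * L
  b_last_end <- b1 + nb * L
  choose_a <- ifelse(has_a & has_b,
                     ifelse(plus, a1 <= b1, a_last_end >= b_last_end),
                     has_a)
  keep <- has_a | has_b
  if (!any(keep))
    return(data.table::data.table(qname = character(), track = character(),
                                  roa_start = integer(), bases = character(),
                                  strand = character()))
  idx <- which(keep)
  trk <- ifelse(choose_a[idx], "A", "B")
  s1 <- ifelse(choose_a[idx], a1[idx], b1[idx])
  cnt <- ifelse(choose_a[idx], na[idx], nb[idx])

  ridx <- rep.int(idx, cnt)
  seg_start <- rep.int(s1, cnt) + (sequence(cnt) - 1L) * L
  rel <- seg_start - apos[ridx] + 1L
  bases <- substring(astr[ridx], rel, rel + L - 1L)
  data.table::data.table(qname = reads$qname[ridx],
                         track = rep.int(trk, cnt),
                         roa_start = as.integer(seg_start),
                         bases = bases,
                         strand = strand[ridx])
}
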