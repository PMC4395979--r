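#' Build a reference set of primary sequences plus allele fragments
#'
#' @param primary Named character vector of primary reference sequences.
#' @param fragments Optional fragment table from [assemble_fragments()]
#'   (anchored to the single primary reference named by `fragment_ref`).
#' @param fragment_ref Name of the primary reference fragments anchor to
#'   (default: first primary).
#' @return data.table with `name`, `seq`, `is_primary`, `anchor_ref`,
#'   `anchor` (0-based; NA for primaries).
#' @export
reference_set <- function(primary, fragments = NULL, fragment_ref = NULL) {
  rs <- data.table::data.table(name = names(primary),
                               seq = unname(primary),
                               is_primary = TRUE,
                               anchor_ref = NA_character_,
                               anchor = NA_integer_)
  if (!is.null(fragments) && nrow(fragments) > 0L) {
    if (is.null(fragment_ref)) fragment_ref <- names(primary)[1]
    fr <- data.table::data.table(
      name = fragment_id(fragment_ref, fragments$anchor, fragments$seq),
      seq = fragments$seq, is_primary = FALSE,
      anchor_ref = fragment_ref, anchor = as.integer(fragments$anchor))
    rs <- rbind(rs, fr[!duplicated(fr$seq)])
  }
  rs
}

#' Map reads with the built-in k-mer seed-and-extend mapper
#'
#' A minimal ungapped mapper for testing and desk-scale runs of the
#' iterative loop (production use plugs in an external aligner through
#' [mapper_adapter()]).  Exact k-mer seeds propose diagonals against every
#' reference; each candidate is scored by Hamming distance over the
#' read/reference overlap.  Reads may overhang reference ends -- the
#' overhang is soft-clipped and mismatches are counted over the overlap
#' only, which is what lets reads longer than an allele fragment still map
#' to it.  Both orientations are tried; the best alignment (highest score,
#' counting +1 per aligned base and -5 net per mismatch, ties to fewest
#' mismatches and then to the primary reference) is
#' reported if it has at most `max_mismatch` mismatches and at least
#' `min_overlap` aligned bases (default 50, so that a clipped alignment
#' still spans at least one full ROA at typical ROA lengths).  No indels.
#'
#' @param reads data.table with `qname` and `seq` (sequencing orientation).
#' @param refset A [reference_set()].
#' @param k Seed length (default 12).
#' @param max_mismatch Maximum mismatches in the overlap (default 2).
#' @param min_overlap Minimum aligned bases (default 30).
#' @return data.table of mapped reads (`qname`, `rname`, `pos` 0-based,
#'   `cigar`, `strand`, `seq` in reference orientation, `nm`, `is_primary`);
#'   unmapped reads are absent.
#' @export
map_reads_kmer <- function(reads, refset, k = 12L, max_mismatch = 2L,
                           min_overlap = 50L) {
  k <- as.integer(k)
  # hash index: k-mer -> integer vector of (ref1, pos1, ref2, pos2, ...)
  idx <- new.env(hash = TRUE, size = 4096L)
  for (ri in seq_len(nrow(refset))) {
    s <- refset$seq[ri]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kms <- substring(s, 1:n, k:(n + k - 1L))
    for (p in seq_len(n)) {
      km <- kms[p]
      idx[[km]] <- c(idx[[km]], ri, p - 1L)
    }
  }
  ref_raw <- lapply(refset$seq, utf8ToInt)
  ref_len <- nchar(refset$seq)
  not_primary <- as.integer(!refset$is_primary)

  # align each distinct sequence once; duplicates share the result
  useq <- unique(reads$seq)
  uidx <- match(reads$seq, useq)
  n_u <- length(useq)
  r_ri <- integer(n_u); r_rs <- integer(n_u)
  r_qs <- integer(n_u); r_ov <- integer(n_u)
  r_mm <- integer(n_u); r_ori <- character(n_u)
  hit <- logical(n_u)

  for (i in seq_len(n_u)) {
    q <- useq[i]
    qlen <- nchar(q)
    if (qlen < k) next
    offs <- unique(c(seq.int(0L, qlen - k, by = k), qlen - k))
    best <- NULL
    for (ori in c("+", "-")) {
      qq <- if (ori == "+") q else revcomp(q)
      qint <- utf8ToInt(qq)
      seeds <- substring(qq, offs + 1L, offs + k)
      seen <- character(0)
      for (si in seq_along(seeds)) {
        h <- idx[[seeds[si]]]
        if (is.null(h)) next
        nh <- length(h) %/% 2L
        for (j in seq_len(nh)) {
          ri <- h[2L * j - 1L]
          diag <- h[2L * j] - offs[si]
          key <- paste0(ri, ":", diag)
          if (key %in% seen) next
          seen <- c(seen, key)
          qs <- max(0L, -diag)
          rs <- max(0L, diag)
          ov <- min(qlen - qs, ref_len[ri] - rs)
          if (ov < min_overlap) next
          mm <- sum(qint[(qs + 1L):(qs + ov)] !=
                      ref_raw[[ri]][(rs + 1L):(rs + ov)])
          if (mm > max_mismatch) next
          # alignment score: +1 per aligned base, net -5 per mismatch, so a
          # longer alignment that accommodates a variant beats a clipped
          # exact one (standard local-alignment economics)
          rank <- c(-(ov - 5L * mm), mm, not_primary[ri], ri, rs)
          if (is.null(best) || lex_less(rank, best$rank))
            best <- list(rank = rank, ri = ri, rs = rs, qs = qs, ov = ov,
                         mm = mm, ori = ori)
        }
      }
    }
    if (is.null(best)) next
    hit[i] <- TRUE
    r_ri[i] <- best$ri; r_rs[i] <- best$rs; r_qs[i] <- best$qs
    r_ov[i] <- best$ov; r_mm[i] <- best$mm; r_ori[i] <- best$ori
  }
  w <- which(hit[uidx])           # reads whose sequence aligned
  if (length(w) == 0L)
    return(data.table::data.table(qname = character(), rname = character(),
                                  pos = integer(), cigar = character(),
                                  strand = character(), seq = character(),
                                  nm = integer(), is_primary = logical()))
  u <- uidx[w]
  qlen <- nchar(reads$seq[w])
  left <- r_qs[u]
  right <- qlen - left - r_ov[u]
  cig <- paste0(ifelse(left > 0L, paste0(left, "S"), ""), r_ov[u], "M",
                ifelse(right > 0L, paste0(right, "S"), ""))
  seqs <- ifelse(r_ori[u] == "+", reads$seq[w], revcomp(reads$seq[w]))
  data.table::data.table(
    qname = reads$qname[w], rname = refset$name[r_ri[u]], pos = r_rs[u],
    cigar = cig, strand = r_ori[u], seq = seqs, nm = r_mm[u],
    is_primary = refset$is_primary[r_ri[u]])
}

lex_less <- function(a, b) {
  d <- a - b
  w <- which(d != 0)[1]
  !is.na(w) && d[w] < 0
}

#' Adapter for an external command-line mapper
#'
#' Wraps a shell command with `{reads}`, `{reference}` and `{out}`
#' placeholders into a mapper usable by [iterate_mapping()].  The command
#' must write a SAM or BAM file; any aligner works, and different adapters
#' may be alternated across iterations.
#'
#' @param command_template Command string with `{reads}`, `{reference}`,
#'   `{out}` placeholders.
#' @param name Adapter name for logs.
#' @param out_ext Extension of the output alignment file (default ".sam").
#' @return A function `(reads, refset, workdir)` returning a mapped-read
#'   table, of class `mapper_adapter`.
#' @export
mapper_adapter <- function(command_template, name = "external",
                           out_ext = ".sam") {
  force(command_template)
  f <- function(reads, refset, workdir = tempdir()) {
    reads_fq <- file.path(workdir, "reads.fastq")
    ref_fa <- file.path(workdir, "refs.fasta")
    out <- file.path(workdir, paste0("mapped", out_ext))
    fq <- data.table::data.table(qname = reads$qname, seq = reads$seq,
                                 strand = "+")
    write_fastq(fq, reads_fq)
    x <- Biostrings::DNAStringSet(refset$seq)
    names(x) <- refset$name
    Biostrings::writeXStringSet(x, ref_fa)
    cmd <- gsub("{reads}", reads_fq, command_template, fixed = TRUE)
    cmd <- gsub("{reference}", ref_fa, cmd, fixed = TRUE)
    cmd <- gsub("{out}", out, cmd, fixed = TRUE)
    # the template may route the aligner's stdout into {out}; only stderr is
    # silenced here
    status <- system(cmd, ignore.stdout = FALSE, ignore.stderr = TRUE)
    if (status != 0L) stop("external mapper '", name, "' failed (exit ",
                           status, "): ", cmd)
    aln <- read_alignments(out, reference_names = refset$name)
    if (nrow(aln) == 0L) stop("external mapper '", name,
                              "' produced no mapped reads")
    # mismatch count against the mapped reference, for deduplication
    aln$nm <- mapply(function(rn, p, cg, sq) {
      a <- aligned_string(sq, cg)
      r <- substr(refset$seq[refset$name == rn], p + 1L, p + nchar(a))
      sum(utf8ToInt(a) != utf8ToInt(r))
    }, aln$rname, aln$pos, aln$cigar, aln$seq, USE.NAMES = FALSE)
    aln$is_primary <- refset$is_primary[match(aln$rname, refset$name)]
    aln
  }
  structure(f, class = c("mapper_adapter", "function"), name = name)
}
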