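# shared fixtures built in code

# read table constructor with defaults
make_reads <- function(pos, seq, strand = "+", qname = NULL, rname = "ref",
                       cigar = NULL) {
  n <- max(length(pos), length(seq), length(strand))
  pos <- rep_len(as.integer(pos), n)
  seq <- rep_len(seq, n)
  strand <- rep_len(strand, n)
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  data.table::data.table(
    qname = if (is.null(qname)) sprintf("r%04d", seq_len(n)) else qname,
    rname = rname, pos = pos, cigar = rep_len(cigar, n),
    strand = strand, seq = seq)
}

# substitute single bases (0-based positions) in a sequence
mutate_seq <- function(seq, pos, alt) {
  for (i in seq_along(pos)) substr(seq, pos[i] + 1L, pos[i] + 1L) <- alt[i]
  seq
}

# deterministic non-reference base
other_base <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]

# segments table for dictionary-level tests
make_segments <- function(track, roa_start, bases, strand, n = 1L) {
  data.table::data.table(
    qname = sprintf("s%05d", seq_len(sum(n))),
    track = rep(track, n), roa_start = rep(as.integer(roa_start), n),
    bases = rep(bases, n), strand = rep(strand, n))
}

# naive per-position pileup from all-M truth-aligned reads: the independent
# oracle for position tallies (counts every read base at every position)
naive_pileup <- function(reads, ref_len) {
  counts <- matrix(0L, nrow = ref_len, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(reads$seq[i], "")[[1]]
    p <- reads$pos[i] + seq_along(b)   # 1-based rows
    for (j in seq_along(b)) {
      counts[p[j], b[j]] <- counts[p[j], b[j]] + 1L
    }
  }
  counts
}

# sequencing-orientation read table for the mapper
to_fastq_table <- function(reads) {
  seq <- reads$seq
  minus <- reads$strand == "-"
  if (any(minus))
    seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[minus])))
  data.table::data.table(qname = reads$qname, seq = seq)
}
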