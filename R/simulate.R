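BASES <- c("A", "C", "G", "T")

#' Packaged synthetic IGHV-like founder sequence
#'
#' A fixed 350-nt synthetic DNA sequence with a realistic density of AID
#' hotspot motifs (WRCY and WA), used as the default founder for the clonal
#' population simulator and in examples.  It is a synthetic stand-in for a
#' clone-specific immunoglobulin heavy-chain variable region: simulations do
#' not depend on its exact composition, only on its length and motif content.
#'
#' @return A character scalar of length-350 DNA.
#' @export
synthetic_founder <- function() {
  paste0(
    "TGCAGCTGGTACCAGTGGTAGCTACTACGCTACTTGGGCTCGGATCTATCCTATGAGTGGTAGCACA",
    "AACTACGCACAGAAGTTCCAGGGCAGAGTCACGATTACCGCGGACAAATCCACGAGCACAGCCTAC",
    "ATGGAGCTGAGCAGCCTGAGATCTGAGGACACGGCCGTGTATTACTGTGCGAGAGATAGCAGTGGC",
    "TGGTACGACTTTTGGAGCGGTTACTACACCGACTACTGGGGCCAGGGAACCCTGGTCACCGTCTCC",
    "TCAGGTGAGTCCTTACAACCTCTCTCTTCTATTCAGCTTAAATAGATTTTACTGCATTTGTTGGGG",
    "GGGAAATGTGTGTATGCGT")
}

#' Synthetic plasmid-like negative-control sequence
#'
#' A fixed, variation-free 1 kb DNA sequence standing in for a spiked-in
#' control plasmid fragment.  At 50,000 100-nt reads this gives about
#' 5,000x coverage, matching a control spiked at roughly one tenth the
#' concentration of the targeted amplicons in an ultra-deep run.  Generated
#' by a small deterministic congruential scheme so the sequence is
#' reproducible without touching R's RNG state.
#'
#' @param length Sequence length in bases (default 1000).
#' @return A character scalar of DNA.
#' @export
synthetic_plasmid <- function(length = 1000L) {
  x <- integer(length)
  s <- 20150312
  for (i in seq_len(length)) {
    s <- (s * 69069 + 1) %% 2147483648
    x[i] <- s %/% 65536 %% 4
  }
  paste0(BASES[x + 1L], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a clonal population by binary replication with mutation
#'
#' Starting from a single founder genome, every lineage is replaced by two
#' copies at each generation, and at every copy event each base mutates
#' independently with probability `mu` to a uniformly chosen different base.
#' After `generations` rounds there are exactly `2^generations` lineages; a
#' mutation acquired at generation `k` is carried (barring later hits at the
#' same site) by `2^(generations - k)` leaves, so truth variant allele
#' frequencies fall on multiples of `2^-generations`.  Back-mutation and
#' homoplasy are possible because draws are independent.
#'
#' @param founder Founder DNA string.
#' @param generations Number of replication rounds (>= 0).
#' @param mu Per-base per-replication mutation probability in `[0, 1)`.
#' @param seed Integer seed (mandatory: simulations are reproducible).
#' @return List of class `clonal_population`: `founder`, `genotypes`
#'   (character vector of `2^generations` lineage genomes), `truth`
#'   (data.table `pos` 0-based, `ref`, `alt`, `vaf`), `generations`, `mu`.
#' @examples
#' pop <- sim_clonal_population(synthetic_founder(), 4, 1e-3, seed = 1)
#' length(pop$genotypes)  # 16
#' @export
sim_clonal_population <- function(founder, generations, mu, seed) {
  stopifnot(generations >= 0, mu >= 0, mu < 1)
  set.seed(as.integer(seed))
  fchars <- strsplit(founder, "")[[1]]
  len <- length(fchars)
  mat <- matrix(fchars, nrow = 1L)
  for (gen in seq_len(generations)) {
    mat <- mat[rep(seq_len(nrow(mat)), each = 2L), , drop = FALSE]
    ncell <- length(mat)
    nmut <- stats::rbinom(1L, ncell, mu)
    if (nmut > 0L) {
      cells <- sample.int(ncell, nmut)
      cur <- mat[cells]
      mat[cells] <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                           character(1), USE.NAMES = FALSE)
    }
  }
  nleaf <- nrow(mat)
  truth <- list()
  for (j in seq_len(len)) {
    col <- mat[, j]
    alt <- col[col != fchars[j]]
    if (length(alt)) {
      tb <- table(alt)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        pos = j - 1L, ref = fchars[j], alt = names(tb),
        vaf = as.numeric(tb) / nleaf)
    }
  }
  truth <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(pos = integer(), ref = character(),
                           alt = character(), vaf = numeric())
  structure(list(founder = founder,
                 genotypes = apply(mat, 1L, paste0, collapse = ""),
                 truth = truth, generations = generations, mu = mu),
            class = "clonal_population")
}

#' Simulate single-ended reads from a set of genomes
#'
#' Reads are drawn from the supplied genomes in proportion to `weights`
#' (uniform by default), with uniform start positions, Bernoulli strand
#' assignment and independent per-base substitution errors.  The returned
#' table is a truth alignment: position and an all-match CIGAR are exact, so
#' the downstream analysis can be exercised with or without a mapper.  `seq`
#' is stored in reference (plus-strand) orientation as in SAM; use
#' [write_fastq()] to obtain sequencing-orientation reads.
#'
#' @param genomes Character vector of genome strings (equal lengths).
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param strand_prob Probability a read is plus-strand (default 0.5).
#' @param seed Integer seed (mandatory).
#' @param weights Sampling weight per genome (default uniform).
#' @param rname Reference name recorded in the alignment (default "ref").
#' @param qname_prefix Read-name prefix.
#' @return data.table with `qname`, `rname`, `pos` (0-based), `cigar`,
#'   `strand`, `seq`, `genome` (1-based source genome index).
#' @export
sim_reads <- function(genomes, n_reads, read_length = 100L, error_rate = 0.001,
                      strand_prob = 0.5, seed, weights = NULL, rname = "ref",
                      qname_prefix = "read") {
  stopifnot(n_reads >= 1, error_rate >= 0, error_rate <= 1)
  set.seed(as.integer(seed))
  glen <- nchar(genomes[1])
  if (any(nchar(genomes) != glen)) stop("genomes must have equal length")
  if (read_length > glen) stop("read_length exceeds genome length")
  gi <- sample.int(length(genomes), n_reads, replace = TRUE, prob = weights)
  starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE) - 1L
  strand <- ifelse(stats::runif(n_reads) < strand_prob, "+", "-")
  seqs <- substring(genomes[gi], starts + 1L, starts + read_length)
  nerr <- stats::rbinom(1L, n_reads * read_length, error_rate)
  if (nerr > 0L) {
    cell <- sample.int(n_reads * read_length, nerr)
    ri <- (cell - 1L) %/% read_length + 1L
    pi <- (cell - 1L) %% read_length + 1L
    for (k in seq_len(nerr)) {
      b <- substr(seqs[ri[k]], pi[k], pi[k])
      substr(seqs[ri[k]], pi[k], pi[k]) <- sample(setdiff(BASES, b), 1L)
    }
  }
  data.table::data.table(
    qname = sprintf("%s_%06d", qname_prefix, seq_len(n_reads)),
    rname = rname, pos = starts, cigar = paste0(read_length, "M"),
    strand = strand, seq = seqs, genome = gi)
}

#' Simulate a variation-free negative control read set
#'
#' Reads from a single sequence with substitution errors only -- the fixture
#' for false-positive testing of the threshold and verification filters
#' (the in-silico analogue of a spiked-in plasmid control).
#'
#' @inheritParams sim_reads
#' @param sequence The control sequence.
#' @return As [sim_reads()].
#' @export
sim_negative_control <- function(sequence, n_reads, read_length = 100L,
                                 error_rate = 0.001, seed, rname = "control") {
  sim_reads(sequence, n_reads, read_length = read_length,
            error_rate = error_rate, seed = seed, rname = rname,
            qname_prefix = "ctl")
}

#' Blend read sets in fixed proportions
#'
#' Draws reads without replacement from each set with multinomial counts
#' proportional to `proportions`, emulating in-silico specimen mixing
#' experiments; truth VAFs of each source rescale by its proportion.
#'
#' @param sets List of read tables (as produced by [sim_reads()]).
#' @param proportions Non-negative mixing weights, one per set.
#' @param total_reads Total reads to draw.
#' @param seed Integer seed.
#' @return A single read table with a `source_set` column.
#' @export
blend_read_sets <- function(sets, proportions, total_reads, seed) {
  stopifnot(length(sets) == length(proportions), all(proportions >= 0))
  set.seed(as.integer(seed))
  counts <- as.vector(stats::rmultinom(1L, total_reads,
                                       proportions / sum(proportions)))
  picked <- lapply(seq_along(sets), function(i) {
    if (counts[i] == 0L) return(NULL)
    n <- nrow(sets[[i]])
    if (counts[i] > n) stop("set ", i, " has too few reads for its share")
    out <- sets[[i]][sample.int(n, counts[i])]
    out$source_set <- i
    out$qname <- paste0("s", i, "_", out$qname)
    out
  })
  data.table::rbindlist(picked)
}
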