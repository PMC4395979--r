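#' Read reference sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read mapped reads from a SAM or BAM file
#'
#' Unmapped, secondary and supplementary records are excluded.  Records whose
#' query-consuming CIGAR length disagrees with the sequence length, or whose
#' sequence is absent, are skipped with a warning and counted.  A reference
#' name absent from `reference_names` is a hard error (it signals a
#' reference/alignment mismatch).  SAM text input is converted with
#' [Rsamtools::asBam()] before parsing.
#'
#' @param path SAM or BAM file.
#' @param reference_names Optional character vector of acceptable reference
#'   names (primary references and fragments).
#' @return data.table with `qname`, `rname`, `pos` (0-based), `cigar`,
#'   `strand`, `seq`; attribute `skipped` counts dropped malformed records.
#' @export
read_alignments <- function(path, reference_names = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                              indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "rname", "pos", "cigar", "strand", "seq"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  dt <- data.table::data.table(
    qname = b$qname, rname = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,              # SAM 1-based -> internal 0-based
    cigar = b$cigar, strand = as.character(b$strand),
    seq = as.character(b$seq))
  qw <- vapply(dt$cigar, query_width, numeric(1), USE.NAMES = FALSE)
  bad <- is.na(dt$seq) | dt$seq == "" | qw != nchar(dt$seq)
  if (any(bad))
    warning(sum(bad), " record(s) skipped: CIGAR/sequence length mismatch")
  dt <- dt[!bad]
  if (!is.null(reference_names) && !all(dt$rname %in% reference_names))
    stop("alignment references unknown reference name(s): ",
         paste(unique(setdiff(dt$rname, reference_names)), collapse = ", "))
  data.table::setattr(dt, "skipped", sum(bad))
  dt
}

#' Write reads as a SAM file
#'
#' Minimal SAM text writer for the read tables used throughout the package
#' (simulated truth alignments and built-in mapper output).  Sequences are
#' written in reference orientation with the strand encoded in FLAG 0x10, as
#' the SAM specification requires.
#'
#' @param reads Read table (`qname`, `rname`, `pos` 0-based, `cigar`,
#'   `strand`, `seq`).
#' @param reference_lengths Named integer vector of reference lengths for the
#'   header.
#' @param path Output file (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                   as.integer(reference_lengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                 reads$qname, flag, reads$rname, reads$pos + 1L,
                 reads$cigar, reads$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write reads as FASTQ (sequencing orientation)
#'
#' Minus-strand reads are reverse-complemented back to sequencing
#' orientation; qualities are constant (the analysis is count-based).
#'
#' @param reads Read table.
#' @param path Output FASTQ file.
#' @param quality_char Constant quality character (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- reads$seq
  minus <- reads$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- reads$qname
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  y <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(y, path)
  invisible(path)
}

#' Read FASTQ reads
#'
#' @param path FASTQ file.
#' @return data.table with `qname` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(qname = sub("\\s.*$", "", names(x)),
                         seq = as.character(x))
}

fragment_id <- function(ref_name, anchor0, seq) {
  # 1-based anchor in the identifier; short content hash for uniqueness
  h <- substr(vapply(seq, function(s)
    sprintf("%08x", sum(utf8ToInt(s) * seq_len(nchar(s))) %% 0xfffffffd),
    character(1), USE.NAMES = FALSE), 1L, 8L)
  sprintf("frag|%s|%d|%s", ref_name, anchor0 + 1L, h)
}

#' Parse an allele-fragment FASTA identifier
#'
#' @param id Identifier of the form `frag|<reference>|<1-based anchor>|<hash>`.
#' @return List with `ref_name` and `anchor` (0-based).
#' @export
parse_fragment_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  if (length(parts) < 3L || parts[1] != "frag")
    stop("not a fragment identifier: ", id)
  list(ref_name = parts[2], anchor = as.integer(parts[3]) - 1L)
}

#' Write the four analysis output files
#'
#' Writes the dictionary CSV (one row per word: reference, 1-based ROA start
#' and end, word sequence, per-strand counts, verification status), the
#' variant CSV (reference, 1-based position, ref/alt base, supporting count,
#' coverage, frequency), the coverage CSV (reference, 1-based position,
#' coverage) and the allele-fragment FASTA whose identifiers encode the
#' reference name and 1-based anchor.  All coordinates in files are 1-based
#' inclusive; internal coordinates are 0-based half-open.
#'
#' @param dictionaries Verified `roa_dictionaries` (or NULL for none).
#' @param variants Variant table from [call_variants()] (or NULL).
#' @param coverage Position coverage table from [tally_positions()] (or NULL).
#' @param fragments Fragment table from [assemble_fragments()] (or NULL).
#' @param reference_name Primary reference name used in all files.
#' @param roa_length ROA length (for dictionary row ends).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_analysis_outputs <- function(dictionaries, variants, coverage, fragments,
                                   reference_name, roa_length, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  paths <- c(dictionary = file.path(out_dir, "dictionary.csv"),
             variants = file.path(out_dir, "variants.csv"),
             coverage = file.path(out_dir, "coverage.csv"),
             fragments = file.path(out_dir, "fragments.fasta"))

  wd <- if (!is.null(dictionaries) && nrow(dictionaries$words) > 0L) {
    w <- dictionaries$words
    data.frame(reference = reference_name, roa_start = w$roa_start + 1L,
               roa_end = w$roa_start + roa_length, word = w$bases,
               plus_count = w$plus, minus_count = w$minus,
               status = if ("status" %in% names(w)) w$status else "raw")
  } else data.frame(reference = character(), roa_start = integer(),
                    roa_end = integer(), word = character(),
                    plus_count = integer(), minus_count = integer(),
                    status = character())
  utils::write.csv(wd, paths["dictionary"], row.names = FALSE, quote = FALSE)

  vd <- if (!is.null(variants) && nrow(variants) > 0L) {
    data.frame(reference = reference_name, position = variants$pos + 1L,
               ref_base = variants$ref, alt_base = variants$alt,
               count = variants$count, coverage = variants$coverage,
               frequency = variants$frequency)
  } else data.frame(reference = character(), position = integer(),
                    ref_base = character(), alt_base = character(),
                    count = integer(), coverage = integer(),
                    frequency = numeric())
  utils::write.csv(vd, paths["variants"], row.names = FALSE, quote = FALSE)

  cd <- if (!is.null(coverage) && nrow(coverage) > 0L) {
    data.frame(reference = reference_name, position = coverage$pos + 1L,
               coverage = coverage$coverage)
  } else data.frame(reference = character(), position = integer(),
                    coverage = integer())
  utils::write.csv(cd, paths["coverage"], row.names = FALSE, quote = FALSE)

  if (!is.null(fragments) && nrow(fragments) > 0L) {
    x <- Biostrings::DNAStringSet(fragments$seq)
    names(x) <- fragment_id(reference_name, fragments$anchor, fragments$seq)
    Biostrings::writeXStringSet(x, paths["fragments"])
  } else {
    file.create(paths["fragments"])
  }
  invisible(paths)
}
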