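#' Rank ROAs by genetic diversity
#'
#' Diversity of an ROA is its number of verified non-reference words; the
#' top-ranked ROA marks the region of highest subclonal diversity.  Ties are
#' broken by the total non-reference read fraction.  Word frequencies are
#' word reads over total ROA coverage.
#'
#' @param dictionaries Verified `roa_dictionaries`.
#' @param collection The [roa_collection()].
#' @param reference Reference sequence string.
#' @param statuses Verification statuses that count as verified (default
#'   fully and partially verified).
#' @return data.table, one row per ROA with any verified non-reference word:
#'   `track`, `roa_start` (0-based), `diversity`, `nonref_fraction`,
#'   `mfc_word`, `mfc_frequency`, ordered by descending diversity.
#' @export
rank_roa_diversity <- function(dictionaries, collection, reference,
                               statuses = c("fully_verified",
                                            "partially_verified_left",
                                            "partially_verified_right")) {
  w <- dictionaries$words
  cov <- dictionaries$coverage
  L <- collection$roa_length
  if (!"status" %in% names(w)) stop("run verify_words() first")
  refword <- substring(reference, w$roa_start + 1L, w$roa_start + L)
  w <- w[w$status %in% statuses & w$bases != refword]
  if (nrow(w) == 0L)
    return(data.table::data.table(track = character(), roa_start = integer(),
                                  diversity = integer(),
                                  nonref_fraction = numeric(),
                                  mfc_word = character(),
                                  mfc_frequency = numeric()))
  m <- cov[w, on = c("track", "roa_start")]
  m$total_cov <- m$plus_cov + m$minus_cov
  m$freq <- (m$plus + m$minus) / m$total_cov
  plus <- minus <- freq <- track <- roa_start <- NULL
  rep_ <- m[, list(diversity = .N, nonref_fraction = sum(freq),
                   mfc_word = bases[which.max(freq)],
                   mfc_frequency = max(freq)),
            by = list(track, roa_start)]
  data.table::setorder(rep_, -diversity, -nonref_fraction)
  rep_
}

#' Export an ROA's words for external phylogenetic analysis
#'
#' Writes the verified words of one ROA as FASTA (reference word included
#' and labeled) plus a CSV of word frequencies, the input expected by
#' maximum-likelihood tree tools; tree inference itself is delegated to
#' external software.
#'
#' @param dictionaries Verified `roa_dictionaries`.
#' @param collection The [roa_collection()].
#' @param reference Reference sequence string.
#' @param track,roa_start The ROA to export.
#' @param fasta_path,csv_path Output paths.
#' @param statuses Verification statuses to export.
#' @return List with the word table, invisibly.
#' @export
export_words_for_phylogeny <- function(dictionaries, collection, reference,
                                       track, roa_start, fasta_path, csv_path,
                                       statuses = c("fully_verified",
                                                    "partially_verified_left",
                                                    "partially_verified_right")) {
  L <- collection$roa_length
  trk <- track
  rs <- as.integer(roa_start)
  w <- data.frame(dictionaries$words)
  cov <- data.frame(dictionaries$coverage)
  w <- w[w$track == trk & w$roa_start == rs & w$status %in% statuses, ]
  refword <- substr(reference, rs + 1L, rs + L)
  cv <- cov[cov$track == trk & cov$roa_start == rs, ]
  total <- cv$plus_cov + cv$minus_cov
  w <- w[w$bases != refword, ]
  labels <- sprintf("word_%02d", seq_len(nrow(w)))
  seqs <- c(refword, w$bases)
  names(seqs) <- c("reference", labels)
  # '-' placeholders are not DNA; exported as-is in a plain FASTA
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, fasta_path)
  tab <- data.frame(label = names(seqs), word = unname(seqs),
                    count = c(NA_integer_, w$plus + w$minus),
                    frequency = c(NA_real_, (w$plus + w$minus) / total))
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  invisible(list(words = tab))
}

IUPAC_W <- c("A", "T")
IUPAC_R <- c("A", "G")
IUPAC_Y <- c("C", "T")

#' Classify an SNV by AID mutational motif
#'
#' AID preferentially deaminates the C of WRCY (W = A/T, R = A/G, Y = C/T)
#' and the A of WA; both motifs act on either strand, so a mutated G whose
#' plus-strand context reads RGYW is the targeted C of a minus-strand WRCY,
#' and a mutated T preceded by T (TW with the T mutated) is the targeted A
#' of a minus-strand WA.  Context is taken from the primary reference; the
#' classification is strand-symmetric by construction.
#'
#' @param reference Reference sequence string.
#' @param pos 0-based position of the mutated base.
#' @param alt_base Alternate base (recorded, not used for classification).
#' @return List of class `motif_call`: `pos`, `ref_base`, `alt_base`,
#'   `motif` (one of `"WRCY_target"`, `"WA_TW_target"`, `"other"`) and
#'   `context` (the reference 4-mer or 2-mer examined, plus-strand).
#' @export
classify_aid_motif <- function(reference, pos, alt_base) {
  n <- nchar(reference)
  at <- function(i) if (i >= 0L && i < n) substr(reference, i + 1L, i + 1L)
    else ""
  b <- at(pos)
  motif <- "other"
  context <- ""
  if (b == "C" && pos >= 2L && pos + 1L < n) {
    # plus-strand WRCY: positions pos-2 (W), pos-1 (R), pos (C), pos+1 (Y)
    ctx <- c(at(pos - 2L), at(pos - 1L), b, at(pos + 1L))
    context <- paste0(ctx, collapse = "")
    if (ctx[1] %in% IUPAC_W && ctx[2] %in% IUPAC_R && ctx[4] %in% IUPAC_Y)
      motif <- "WRCY_target"
  } else if (b == "G" && pos >= 1L && pos + 2L < n) {
    # minus-strand WRCY reads RGYW on the plus strand with the G targeted
    ctx <- c(at(pos - 1L), b, at(pos + 1L), at(pos + 2L))
    context <- paste0(ctx, collapse = "")
    if (ctx[1] %in% IUPAC_R && ctx[3] %in% IUPAC_Y && ctx[4] %in% IUPAC_W)
      motif <- "WRCY_target"
  }
  if (motif == "other" && b == "A" && pos >= 1L) {
    context <- paste0(at(pos - 1L), b)
    if (at(pos - 1L) %in% IUPAC_W) motif <- "WA_TW_target"
  }
  if (motif == "other" && b == "T" && pos + 1L < n) {
    # minus-strand WA reads TW on the plus strand with the T targeted
    context <- paste0(b, at(pos + 1L))
    if (at(pos + 1L) %in% IUPAC_W) motif <- "WA_TW_target"
  }
  structure(list(pos = pos, ref_base = b, alt_base = alt_base,
                 motif = motif, context = context),
            class = "motif_call")
}

#' One-tailed Fisher exact test from the hypergeometric tail
#'
#' Exact upper-tail probability of observing at least `a` motif-position
#' mutations in a 2x2 table (mutated vs unmutated positions crossed with
#' motif-eligible vs other positions), computed from log binomial
#' coefficients.  This is the enrichment test used on AID motif calls.
#'
#' @param a Mutated positions at motif-eligible sites.
#' @param b Mutated positions at other sites.
#' @param c_ Unmutated motif-eligible positions.
#' @param d Unmutated other positions.
#' @return One-tailed p-value (enrichment).
#' @export
fisher_tail <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  n <- a + b + c_ + d
  m <- a + c_          # motif-eligible positions
  kk <- a + b          # mutated positions
  hi <- min(kk, m)
  ks <- a:hi
  # P(X = k) for hypergeometric draws of kk from m eligible / (n - m) other
  logp <- lchoose(m, ks) + lchoose(n - m, kk - ks) - lchoose(n, kk)
  sum(exp(logp))
}

#' Test AID-motif enrichment among variant calls
#'
#' Classifies every call with [classify_aid_motif()], counts motif-eligible
#' reference positions (a position is WRCY-eligible if it is the targeted
#' C/G of a WRCY/RGYW context, WA/TW-eligible likewise), builds the 2x2
#' table of mutated vs unmutated positions against eligible vs other, and
#' returns the one-tailed Fisher exact p-value per motif class.  Position
#' counting is per reference site; a site with calls in several alternate
#' bases is one mutated site.
#'
#' @param calls Variant table with `pos` (0-based) and `alt` columns.
#' @param reference Reference sequence string.
#' @return data.table with one row per motif class: counts of the 2x2 table
#'   and `p_value`.
#' @export
motif_enrichment_test <- function(calls, reference) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no variant calls supplied")
  n <- nchar(reference)
  site_class <- vapply(0:(n - 1L),
                       function(p) classify_aid_motif(reference, p, "N")$motif,
                       character(1))
  mut_pos <- unique(calls$pos)
  mutated <- (0:(n - 1L)) %in% mut_pos
  out <- lapply(c("WRCY_target", "WA_TW_target"), function(cls) {
    elig <- site_class == cls
    a <- sum(mutated & elig); b <- sum(mutated & !elig)
    c_ <- sum(!mutated & elig); d <- sum(!mutated & !elig)
    data.table::data.table(motif = cls, mutated_eligible = a,
                           mutated_other = b, unmutated_eligible = c_,
                           unmutated_other = d,
                           p_value = fisher_tail(a, b, c_, d))
  })
  data.table::rbindlist(out)
}
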