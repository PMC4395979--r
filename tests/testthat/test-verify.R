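# hand-constructed fixture: reference of 102 nt, ROA length 34, so track A
# covers [0,34),[34,68),[68,102) and track B covers [17,51),[51,85).
fixture_ref <- function() {
  paste0(strrep("AC", 25), strrep("GT", 26))  # 102 nt, non-repetitive halves
}

# build verified dictionaries from explicit (track, start, word, n+) tuples;
# every word gets balanced strands so thresholds are irrelevant here
fixture_dicts <- function(spec, collection) {
  segs <- data.table::rbindlist(lapply(seq_len(nrow(spec)), function(i) {
    make_segments(spec$track[i], spec$start[i], spec$word[i],
                  rep(c("+", "-"), each = spec$n[i]))
  }))
  segs$qname <- sprintf("q%05d", seq_len(nrow(segs)))
  verify_words(build_dictionaries(segs), collection)
}

word_of <- function(ref, s, mut_pos = integer(0), alt = character(0)) {
  w <- substr(ref, s + 1, s + 34)
  for (i in seq_along(mut_pos))
    substr(w, mut_pos[i] - s + 1, mut_pos[i] - s + 1) <- alt[i]
  w
}

test_that("half-word matching across independent tracks sets verification status", {
  ref <- fixture_ref()
  col <- roa_collection("ref", 102, 34)
  # variant at position 20: left half of B[17,51) ([17,34)), right half of
  # A[0,34); a matching variant word in A[0,34) fully verifies the B word
  # (its right half is pure reference, matched by A[34,68) reference word)
  spec <- data.frame(
    track = c("B", "A", "A", "B", "A"),
    start = c(17L, 0L, 34L, 51L, 68L),
    word = c(word_of(ref, 17, 20, "T"), word_of(ref, 0, 20, "T"),
             word_of(ref, 34), word_of(ref, 51), word_of(ref, 68)),
    n = c(10L, 10L, 50L, 50L, 50L))
  v <- fixture_dicts(spec, col)
  w <- v$words
  stat <- function(trk, s, word) w$status[w$track == trk & w$roa_start == s &
                                          w$bases == word]
  expect_equal(stat("B", 17L, word_of(ref, 17, 20, "T")), "fully_verified")
  # the A[0,34) variant word: no left-overlap ROA exists (span boundary),
  # right half is reference and matches B words -> partial right at best
  expect_equal(stat("A", 0L, word_of(ref, 0, 20, "T")),
               "partially_verified_right")

  # a variant present in only one ROA's reads is never fully verified
  spec2 <- rbind(spec,
                 data.frame(track = "B", start = 17L,
                            word = word_of(ref, 17, 40, "G"), n = 10L))
  v2 <- fixture_dicts(spec2, col)
  w2 <- v2$words
  st <- w2$status[w2$bases == word_of(ref, 17, 40, "G")]
  # its right half carries the lone variant: no A[34,68) match exists
  expect_false(st == "fully_verified")
})

test_that("reference words in an error-free simulation verify fully in the interior", {
  ref <- synthetic_plasmid(400)
  rd <- sim_reads(ref, 4000, read_length = 100, error_rate = 0, seed = 2,
                  rname = "ref")
  an <- analyze_reads(rd, c(ref = ref), roa_length = 34)
  w <- an$dictionaries$words
  # boundary ROAs are strand-starved by the 5'-nearest assignment rule and
  # lack one verifier; restrict to ROAs a full read length from the ends
  interior <- w$roa_start >= 100 & w$roa_start + 34 <= 300
  expect_gt(sum(interior), 5L)
  expect_true(all(w$status[interior] == "fully_verified"))
})

test_that("N-containing or gapped halves never match", {
  ref <- fixture_ref()
  col <- roa_collection("ref", 102, 34)
  wN <- word_of(ref, 17); substr(wN, 5, 5) <- "N"
  wA <- word_of(ref, 0); substr(wA, 22, 22) <- "N"
  spec <- data.frame(track = c("B", "A", "A"),
                     start = c(17L, 0L, 34L),
                     word = c(wN, wA, word_of(ref, 34)),
                     n = c(10L, 10L, 10L))
  v <- fixture_dicts(spec, col)
  w <- v$words
  # B word's left half has N: cannot match A[0,34) even though the N sits
  # at the same place in both; right half (reference) still matches
  expect_equal(w$status[w$bases == wN], "partially_verified_right")
})

test_that("fragment assembly produces all verifier combinations of 2L length", {
  ref <- fixture_ref()
  col <- roa_collection("ref", 102, 34)
  # central word carries one variant in each half: 40 (A>G) and 60 (G>C)
  central <- word_of(ref, 34, c(40, 60), c("G", "C"))
  # left verifiers: right halves must equal the central left half
  lv1 <- word_of(ref, 17, 40, "G")
  lv2 <- word_of(ref, 17, c(40, 20), c("G", "T"))  # extra variant outside the overlap
  # right verifiers: left halves must equal the central right half
  rv1 <- word_of(ref, 51, 60, "C")
  rv2 <- word_of(ref, 51, c(60, 80), c("C", "A"))
  rv3 <- word_of(ref, 51, c(60, 82), c("C", "C"))
  spec <- data.frame(
    track = c("A", "B", "B", "B", "B", "B", "A", "A"),
    start = c(34L, 17L, 17L, 51L, 51L, 51L, 0L, 68L),
    word = c(central, lv1, lv2, rv1, rv2, rv3,
             word_of(ref, 0), word_of(ref, 68)),
    n = c(20L, 10L, 10L, 10L, 10L, 10L, 50L, 50L))
  v <- fixture_dicts(spec, col)
  expect_equal(v$words$status[v$words$bases == central], "fully_verified")
  fr <- assemble_fragments(v, col, ref)
  mine <- fr[fr$central_start == 34L & fr$central_track == "A"]
  # central variant word: 2 left matches x 3 right matches = 6 fragments
  expect_equal(nrow(mine), 6L)
  expect_true(all(nchar(mine$seq) == 68L))
  expect_true(all(mine$anchor == 17L))
  # fragment center equals the central word
  expect_true(all(substr(mine$seq, 18, 51) == central))
})

test_that("reference-identical fragments are suppressed", {
  ref <- fixture_ref()
  col <- roa_collection("ref", 102, 34)
  spec <- data.frame(track = c("A", "B", "B", "A", "A"),
                     start = c(34L, 17L, 51L, 0L, 68L),
                     word = c(word_of(ref, 34), word_of(ref, 17),
                              word_of(ref, 51), word_of(ref, 0),
                              word_of(ref, 68)),
                     n = 50L)
  v <- fixture_dicts(spec, col)
  expect_true(all(v$words$status[v$words$roa_start == 34] == "fully_verified"))
  fr <- assemble_fragments(v, col, ref)
  expect_equal(nrow(fr), 0L)
})

test_that("non-fully-verified words spawn reference-padded fragments above the acceptance share", {
  ref <- fixture_ref()
  col <- roa_collection("ref", 102, 34)
  lone <- word_of(ref, 34, c(40, 60), c("G", "C"))
  spec <- data.frame(track = c("A", "A", "B", "B"),
                     start = c(34L, 34L, 17L, 51L),
                     word = c(lone, word_of(ref, 34), word_of(ref, 17),
                              word_of(ref, 51)),
                     n = c(20L, 30L, 50L, 50L))
  v <- fixture_dicts(spec, col)
  expect_equal(v$words$status[v$words$bases == lone], "unverified")
  # share 40% >= 10%: reference-left + word + reference-right
  fr <- assemble_fragments(v, col, ref, accept_prop = 0.10)
  mine <- fr[fr$central_start == 34L]
  expect_equal(nrow(mine), 1L)
  expect_equal(mine$seq,
               paste0(substr(ref, 18, 34), lone, substr(ref, 69, 85)))
  # share gate: at accept_prop above the word's 40% share, nothing is built
  fr2 <- assemble_fragments(v, col, ref, accept_prop = 0.5)
  expect_equal(nrow(fr2[fr2$central_start == 34L]), 0L)
})

test_that("fragments never invent sequence and exclude gapped or N words", {
  ref <- synthetic_plasmid(300)
  var <- mutate_seq(ref, c(100, 140), c(other_base(substr(ref, 101, 101)),
                                        other_base(substr(ref, 141, 141))))
  rd <- sim_reads(c(ref, var), 6000, read_length = 80, error_rate = 0.001,
                  seed = 9, weights = c(0.7, 0.3), rname = "ref")
  col <- roa_collection("ref", 300, 34)
  segs <- assign_reads(rd, col)
  d <- verify_words(threshold_words(build_dictionaries(segs),
                                    threshold_params(750, 2)), col)
  fr <- assemble_fragments(d, col, ref)
  expect_gt(nrow(fr), 0L)
  expect_false(any(grepl("[N-]", fr$seq)))
  # every fragment base agrees with reference or some retained word at that
  # genomic position
  allowed <- lapply(seq_len(300), function(p) substr(ref, p, p))
  for (i in seq_len(nrow(d$words))) {
    s <- d$words$roa_start[i]
    b <- strsplit(d$words$bases[i], "")[[1]]
    for (j in seq_along(b))
      allowed[[s + j]] <- union(allowed[[s + j]], b[j])
  }
  for (i in seq_len(nrow(fr))) {
    b <- strsplit(fr$seq[i], "")[[1]]
    ok <- vapply(seq_along(b),
                 function(j) b[j] %in% allowed[[fr$anchor[i] + j]], logical(1))
    expect_true(all(ok))
  }
})

test_that("verification depends only on dictionaries, not read partitioning", {
  ref <- synthetic_plasmid(300)
  var <- mutate_seq(ref, 150, other_base(substr(ref, 151, 151)))
  rd <- sim_reads(c(ref, var), 4000, read_length = 80, error_rate = 0,
                  seed = 13, weights = c(0.8, 0.2), rname = "ref")
  col <- roa_collection("ref", 300, 34)
  d <- threshold_words(build_dictionaries(assign_reads(rd, col)),
                       threshold_params(750, 2))
  v1 <- verify_words(d, col)
  # shuffle read order and rebuild: same dictionaries, same statuses
  rd2 <- rd[sample.int(nrow(rd))]
  d2 <- threshold_words(build_dictionaries(assign_reads(rd2, col)),
                        threshold_params(750, 2))
  v2 <- verify_words(d2, col)
  k1 <- v1$words[order(track, roa_start, bases)]
  k2 <- v2$words[order(track, roa_start, bases)]
  expect_equal(k1$status, k2$status)
  expect_equal(k1$bases, k2$bases)
})
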