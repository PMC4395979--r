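test_that("reference-only dictionaries yield full-reference tallies and no calls", {
  ref <- synthetic_plasmid(200)
  rd <- sim_reads(ref, 2000, read_length = 80, error_rate = 0, seed = 4,
                  rname = "ref")
  an <- analyze_reads(rd, c(ref = ref), roa_length = 34)
  expect_equal(nrow(an$variants), 0L)
  tal <- an$tally
  refb <- substring(ref, tal$pos + 1L, tal$pos + 1L)
  expect_true(all(tal$base == refb))
})

test_that("a verified variant word at known counts gives the expected frequency", {
  # both covering ROAs hold the variant word at 100 of 10,000 reads; the
  # tally sums the two tracks, so frequency is exactly 0.01
  ref <- paste0(strrep("AC", 25), strrep("GT", 26))
  col <- roa_collection("ref", 102, 34)
  vb <- "G"  # at position 40 (reference A)
  wA <- substr(ref, 35, 68); substr(wA, 7, 7) <- vb   # A[34,68)
  wB <- substr(ref, 18, 51); substr(wB, 24, 24) <- vb # B[17,51)
  segs <- data.table::rbindlist(list(
    make_segments("A", 34L, substr(ref, 35, 68), rep(c("+", "-"), 4950)),
    make_segments("A", 34L, wA, rep(c("+", "-"), 50)),
    make_segments("B", 17L, wB, rep(c("+", "-"), 50)),
    make_segments("B", 17L, substr(ref, 18, 51), rep(c("+", "-"), 4950)),
    make_segments("A", 0L, substr(ref, 1, 34), rep(c("+", "-"), 200)),
    make_segments("B", 51L, substr(ref, 52, 85), rep(c("+", "-"), 200)),
    make_segments("A", 68L, substr(ref, 69, 102), rep(c("+", "-"), 200))))
  segs$qname <- sprintf("q%06d", seq_len(nrow(segs)))
  v <- verify_words(build_dictionaries(segs), col)
  tal <- tally_positions(v, col)
  vc <- call_variants(tal, ref)
  hit <- vc[vc$pos == 40L]
  expect_equal(hit$alt, vb)
  expect_equal(hit$count, 200L)
  expect_equal(hit$coverage, 20000L)
  expect_equal(hit$frequency, 0.01)
})

test_that("deletion symbols feed a deletion tally, and counts conserve coverage", {
  col <- roa_collection("ref", 102, 34)
  wdel <- paste0(strrep("A", 10), "-", strrep("A", 23))
  segs <- data.table::rbindlist(list(
    make_segments("A", 34L, strrep("A", 34), rep(c("+", "-"), 30)),
    make_segments("A", 34L, wdel, rep(c("+", "-"), 10))))
  segs$qname <- sprintf("q%05d", seq_len(nrow(segs)))
  d <- build_dictionaries(segs)
  tal <- tally_positions(d, col, eligibility = "all")
  at44 <- tal$tally[tal$tally$pos == 44L]
  expect_setequal(at44$base, c("A", "-"))
  expect_equal(sum(at44$count), tal$coverage$coverage[tal$coverage$pos == 44L])
  # '-' never becomes an SNV call
  vc <- call_variants(tal, strrep("C", 102))
  expect_false(any(vc$alt == "-"))
})

test_that("multiple alternate bases at one site are each reported", {
  ref <- synthetic_plasmid(300)
  p <- 150L
  rb <- substr(ref, p + 1, p + 1)
  alts <- setdiff(c("A", "C", "G", "T"), rb)[1:2]
  v1 <- mutate_seq(ref, p, alts[1])
  v2 <- mutate_seq(ref, p, alts[2])
  # two subclones at 0.5% each over a deep wild-type background
  rd <- sim_reads(c(ref, v1, v2), 60000, read_length = 100,
                  error_rate = 0, seed = 21,
                  weights = c(0.99, 0.005, 0.005), rname = "ref")
  an <- analyze_reads(rd, c(ref = ref), roa_length = 34, min_vaf = 0.003)
  hits <- an$variants[an$variants$pos == p]
  expect_setequal(hits$alt, alts)
  expect_true(all(hits$frequency > 0.003 & hits$frequency < 0.008))
})

test_that("the minimum-frequency cut is a strict threshold", {
  ref <- paste0(strrep("AC", 25), strrep("GT", 26))
  col <- roa_collection("ref", 102, 34)
  wA <- substr(ref, 35, 68); substr(wA, 7, 7) <- "G"
  wB <- substr(ref, 18, 51); substr(wB, 24, 24) <- "G"
  segs <- data.table::rbindlist(list(
    make_segments("A", 34L, substr(ref, 35, 68), rep(c("+", "-"), 751)),
    make_segments("A", 34L, wA, rep(c("+", "-"), 249)),
    make_segments("B", 17L, wB, rep(c("+", "-"), 249)),
    make_segments("B", 17L, substr(ref, 18, 51), rep(c("+", "-"), 751)),
    make_segments("A", 0L, substr(ref, 1, 34), rep(c("+", "-"), 200)),
    make_segments("B", 51L, substr(ref, 52, 85), rep(c("+", "-"), 200))))
  segs$qname <- sprintf("q%06d", seq_len(nrow(segs)))
  v <- verify_words(build_dictionaries(segs), col)
  tal <- tally_positions(v, col)
  expect_equal(nrow(call_variants(tal, ref, min_vaf = 0.25)), 0L)  # 24.9%
  expect_equal(nrow(call_variants(tal, ref, min_vaf = 0.24)), 1L)
})

test_that("homozygous variants on error-free reads reach frequency 1", {
  ref <- synthetic_plasmid(200)
  hom <- mutate_seq(ref, 100, other_base(substr(ref, 101, 101)))
  rd <- sim_reads(hom, 2000, read_length = 80, error_rate = 0, seed = 6,
                  rname = "ref")
  an <- analyze_reads(rd, c(ref = ref), roa_length = 34)
  hit <- an$variants[an$variants$pos == 100L]
  expect_equal(hit$frequency, 1)
})

test_that("with verification disabled the tally equals a naive pileup exactly", {
  # reads placed on the half-ROA grid with length 2L always contribute their
  # entire footprint, so word tallies must reproduce the raw pileup
  set.seed(33)
  ref <- synthetic_plasmid(306)
  var <- mutate_seq(ref, c(60, 150), c(other_base(substr(ref, 61, 61)),
                                       other_base(substr(ref, 151, 151))))
  starts <- sample(seq(0L, 306L - 68L, by = 17L), 3000, TRUE)
  gi <- sample(1:2, 3000, TRUE, prob = c(0.9, 0.1))
  g <- c(ref, var)
  reads <- make_reads(starts, substring(g[gi], starts + 1L, starts + 68L),
                      strand = sample(c("+", "-"), 3000, TRUE))
  col <- roa_collection("ref", 306, 34)
  d <- build_dictionaries(assign_reads(reads, col))
  tal <- tally_positions(d, col, eligibility = "all")
  pile <- naive_pileup(reads, 306)
  for (b in c("A", "C", "G", "T")) {
    got <- integer(306)
    rows <- tal$tally[tal$tally$base == b]
    got[rows$pos + 1L] <- rows$count
    expect_equal(got, unname(pile[, b]))
  }
  # with verification enabled, calls are a subset of pileup alternates
  vd <- verify_words(threshold_words(d, threshold_params(400, 2)), col)
  vc <- call_variants(tally_positions(vd, col), ref)
  for (i in seq_len(nrow(vc)))
    expect_gt(pile[vc$pos[i] + 1L, vc$alt[i]], 0L)
})

test_that("frequency estimates are unbiased within binomial error", {
  ref <- synthetic_plasmid(250)
  p <- 120L
  alt <- other_base(substr(ref, p + 1, p + 1))
  var <- mutate_seq(ref, p, alt)
  f <- 0.05
  inside <- 0L
  for (r in 1:20) {
    rd <- sim_reads(c(ref, var), 6000, read_length = 80, error_rate = 0.001,
                    seed = 100 + r, weights = c(1 - f, f), rname = "ref")
    an <- analyze_reads(rd, c(ref = ref), roa_length = 34)
    hit <- an$variants[an$variants$pos == p & an$variants$alt == alt]
    if (nrow(hit) == 1L) {
      half <- 4 * sqrt(f * (1 - f) / hit$coverage)
      if (abs(hit$frequency - f) <= half) inside <- inside + 1L
    }
  }
  expect_gte(inside, 19L)
})
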