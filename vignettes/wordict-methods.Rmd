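---
title: "Word-dictionary variant detection in hypermutated regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-dictionary variant detection in hypermutated regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordict)
```

## The problem

Regions under somatic hypermutation (immunoglobulin loci in B-cell
lymphomas, kataegis loci in other cancers) present two coupled obstacles to
variant analysis.  First, subclonal variants of interest sit at allele
frequencies (VAF) below 1%, inside the noise floor of per-base sequencing
error, so site-by-site callers must either raise their thresholds or drown
in false positives.  Second, the same regions carry *clustered* variation:
reads from a divergent subclone can differ from the reference at five or
more positions within a read length, and aligners with bounded mismatch
budgets simply fail to map them.  The missing reads silently delete the
most interesting subclones from the data and bias downward the frequency
estimates of everything that does map.

`wordict` addresses both problems with one data structure: local haplotype
*words* collected per fixed window of the reference, filtered by replicated
observation, and recycled as alternate reference sequences for iterative
remapping.

## Regions of analysis and words

A reference sequence is partitioned into *regions of analysis* (ROAs):
fixed, even-length windows of length $L$ arranged in two tracks of abutting
windows, track B shifted by $L/2$ relative to track A.  Every interior
position is therefore covered by exactly one ROA of each track, and the two
ROAs covering it overlap each other by half their length.

Each mapped read is assigned to **one** ROA track: among the ROAs fully
contained in the read's reference footprint (CIGAR-aware; deletions cover
reference, insertions and soft clips do not), the ROA whose start is
nearest the read's 5' end in read orientation wins, and the read is trimmed
to that ROA — or split across further abutting same-track ROAs it fully
covers.  Insertions relative to the reference are dropped; deleted
reference bases are rendered as `-`.  Reads too short to cover any ROA
contribute nothing.

The segments of an ROA are compressed into a *dictionary*: the set of
distinct ROA-length strings (*words*) with per-strand occurrence counts.
Count conservation is exact: per-strand word counts sum to per-strand ROA
coverage.

The point of the unique-track rule is statistical, not bookkeeping: the two
dictionaries covering any position are built from **disjoint read sets**,
which is what makes the cross-verification below an independent
replication test.

## Filtering

**Bidirectional threshold.**  A word is retained only if, on *each* strand
separately, its count reaches

$$T_s = \max\left(a_{\min},\ \lceil \mathrm{ppm} \times 10^{-6} \times
C_s\rceil\right),$$

where $C_s$ is the per-strand ROA coverage.  Words seen on one strand only
are always discarded — strand bias is the signature of process error.  The
relative part (in parts per million) governs at deep coverage; the absolute
minimum $a_{\min}$ governs at shallow coverage.  Two settings are used: a
stringent one (default 750 ppm) while generating remapping fragments, where
a false fragment costs iterations, and a permissive one (default 400 ppm)
for final variant discovery.  Defaults: $a_{\min} = 2$ per strand, the
smallest value that still demands replication within each direction;
`ceiling` is used so a count must strictly meet the proportional bar.

**Cross-verification.**  Each thresholded word is split into halves.  Its
left half occupies the same genomic interval as the right half of words in
the other track's left-overlapping ROA; likewise on the right.  A half
*matches* when the $L/2$-mers are exactly equal (halves containing `N` or
`-` never match).  Words matching on both sides are *fully verified*, on
one side *partially verified*, otherwise *unverified*.  Because the
overlapping dictionaries come from disjoint reads, a fully verified word
has every variant it carries reproduced independently on both flanks.
ROAs at the ends of the analyzed span lack one neighbor and can at best be
partially verified; the variant caller's `eligibility = "partial"` option
exists for exactly those positions.

## Allele fragments and iterative remapping

Fully verified words are extended into *allele fragments* of length $2L$:
every combination of a matching left verifier's left half, the central
word, and a matching right verifier's right half, anchored at reference
coordinates.  Partially verified and unverified words are extended with
reference sequence on their unmatched side(s), but only when the central
word accounts for at least `accept_prop` of its ROA coverage.  Fragments
equal to the reference window are suppressed; words containing `N` or `-`
never become fragments (fragments must be plain DNA for an aligner).

The iteration loop is: map all reads against the current reference set
(primary plus accumulated fragments), lift fragment alignments back to
primary coordinates through the fragment anchor (fragments are gap-free, so
the lift is an offset), deduplicate multi-mapped reads (fewest mismatches,
ties to the primary), rebuild dictionaries, filter at the iterative
threshold, verify, assemble fragments, and repeat until the set of
iterative-threshold words stops changing (equivalently, until no new
fragments appear — mapping is deterministic, so an unchanged reference set
is a fixed point).  A hard cap (`max_iter = 10`) bounds the loop.  After
convergence the last mapping is re-analyzed at the permissive threshold for
variant discovery.

### Why `accept_prop` defaults to 0.02

The acceptance gate for non-fully-verified fragments must separate two
populations: noise words that squeaked past the iterative threshold (their
coverage share is bounded by roughly the threshold scale, $\sim$0.1–0.3% at
750 ppm) and genuine subclone words.  The subtlety is that a subclone
word's *apparent* share is attenuated by the very mapping failure iteration
exists to repair: while every wild-type read over an ROA maps, often only a
narrow window of the subclone's reads (those carrying few enough cluster
variants to fit the mismatch budget) maps at all.  In a typical
dense-cluster scenario a 40%-VAF subclone surfaces at a 2–4% coverage
share at the iteration frontier.  A 10% gate silently stalls the cascade; a
2% gate is still an order of magnitude above the noise-word scale and
admits subclones down to roughly 5–10% VAF under severe attenuation.  The
parameter is exposed (`--fragment-accept-prop`) for more conservative runs.

### The built-in mapper

Production use plugs external aligners in through `mapper_adapter()` (any
command that reads FASTQ and writes SAM/BAM; different aligners may be
alternated between iterations).  For testing and desk-scale work the
package ships a deliberately minimal ungapped seed-and-extend mapper:
exact $k$-mer seeds propose diagonals, candidates are scored by Hamming
distance over the read/reference overlap, both orientations are tried, and
overhangs beyond reference ends are soft-clipped with mismatches counted
over the overlap only — without which no read longer than a $2L$ fragment
could ever map to one.  Two scoring choices matter:

* candidates are ranked by alignment score (+1 per aligned base, net −5
  per mismatch), not by fewest mismatches.  Fewest-first systematically
  prefers clipping a read back into already-known fragment territory over
  extending across a new variant — the new variant *is* the mismatch — and
  deadlocks the iteration frontier.  Score ranking is also how production
  aligners behave.
* `min_overlap` (default 50) keeps clipped alignments long enough to span
  at least one full ROA at typical geometries, so a mapped read is never
  pure bookkeeping.

ROA length should be chosen so that fragments are at least as long as the
reads ($2L \geq$ read length): 34-nt ROAs pair naturally with 50-nt reads,
and longer reads warrant proportionally longer ROAs (or acceptance of
clipped fragment alignments, which slightly biases tally composition
between the tracks).  $L$ must also be small enough that a single ROA
rarely holds more cluster variants than the mapper's mismatch budget, or
the frontier cannot advance at all.

## Variant calling

Verified words are tallied per position: a word contributes its total count
to its base at each position it spans; the two ROAs covering a position
come from disjoint read sets, so summing both tracks counts each read at
most once.  `-` and `N` feed separate tallies and never support a base
call; base counts plus those tallies conserve coverage exactly.  Every
(position, alternate base) pair above the count and frequency cuts is
reported — multi-allelic sites are real and common in hypermutated regions,
where independent subclones hit the same hotspot base differently, and are
deliberately *not* collapsed to the single most frequent alternate.  The
reference base always comes from the primary reference, never from a
fragment.

## Subclones and mutational motifs

Per-ROA dictionaries double as subclone reports: the number of verified
non-reference words in an ROA is a direct diversity measure, and
`rank_roa_diversity()` orders ROAs by it (ties broken by total
non-reference read fraction).  `export_words_for_phylogeny()` writes one
ROA's words with the reference as FASTA plus a frequency CSV for external
maximum-likelihood tree tools; tree inference itself is intentionally out
of scope.

SNVs are classified against the AID hotspot motifs WRCY (W = A/T, R = A/G,
Y = C/T; the C is targeted) and WA (the A is targeted), on either strand:
a mutated G in a plus-strand RGYW context is the targeted C of a
minus-strand WRCY, and a mutated T followed by W (the TW context) is the
targeted A of a minus-strand WA.  Context is read from the primary
reference, which keeps the classification reproducible even where a
mutation creates or destroys a motif.  Enrichment is tested with a
one-tailed Fisher exact test implemented from the hypergeometric tail via
log binomial coefficients: the 2x2 table crosses mutated vs unmutated
reference positions with motif-eligible vs other positions, counting per
site (a multi-allelic site is one mutated site).  The per-site construction
is a documented interpretation; per-mutation counting is equally defensible
and gives very similar tails on realistic inputs.

## The synthetic-data generator

`sim_clonal_population()` models ongoing mutation as binary replication:
each generation every lineage is replaced by two copies, and each copy
event mutates every base independently with probability $\mu$ to a
uniformly chosen different base.  After $g$ generations there are exactly
$2^g$ lineages and a mutation acquired at generation $k$ survives in
$2^{g-k}$ leaves, so truth VAFs fall on multiples of $2^{-g}$ — with
$g = 10$, from 100% down to $1/1024 \approx 0.098\%$.  Back-mutation and
homoplasy are possible because draws are independent.  The default founder
is a packaged synthetic 350-nt immunoglobulin-heavy-chain-like sequence
with realistic WRCY/WA motif density; the default study design uses
$\mu = 10^{-4}$ per base per copy event.

`sim_reads()` draws single-ended reads with uniform starts, Bernoulli(0.5)
strand, and independent uniform substitution errors (default 0.1% per
base), returning a *truth alignment* (exact positions, all-match CIGARs) so
the analysis core can be exercised with or without a mapper.
`sim_negative_control()` is the same machine pointed at a single
variation-free sequence — the packaged 1-kb plasmid-like control at 50,000
reads gives ~5,000x coverage, emulating a control spiked at a tenth of the
amplicon concentration of an ultra-deep run.  `blend_read_sets()` mixes
read sets without replacement in multinomial proportions, rescaling truth
VAFs by the mixing weights.

What the generator deliberately does **not** model: PCR amplification bias
and duplicate structure, indel errors, position- or context-dependent error
profiles (the optional 3'-ramp of real instruments), quality-string
information (the method is count-based), and paired-end structure.
Consequently, passing simulations demonstrate the combinatorial and
statistical behavior of the filters and the iteration — not robustness to
platform-specific artifacts, which in real data is delegated to the
upstream aligner and to the strand-bias and replication requirements of the
threshold filter.

## Numerical and boundary choices

* Internal coordinates are 0-based half-open; all report files are 1-based
  inclusive, matching SAM conventions.
* When both tracks offer an equally near candidate ROA, track A wins
  (determinism).
* The read-assignment rule is deterministic in the footprint, which at the
  ends of the analyzed span systematically routes one strand's reads to one
  track: the outermost ROAs are strand-starved and their words legitimately
  fail the bidirectional threshold.  Together with the missing outer
  verifier, positions within about a read length of the span ends have
  reduced, and in the outer half-ROA no, fully-verified coverage.
  Quantitative evaluations in the package therefore report over interior
  windows; real studies should place amplicon boundaries a read length
  outside the region of interest.
* Convergence compares word *sets*, not counts.
* At 10,000x positional coverage the per-strand per-ROA coverage of a
  34-nt ROA is roughly a quarter of that, and a variant at VAF $1/1024$
  expects only ~2 reads per strand per covering ROA.  Since a call needs
  the absolute minimum (2 per strand) cleared in *both* covering ROAs,
  sensitivity at the deepest dyadic frequencies is Poisson-limited there;
  it recovers with coverage (the relative ppm threshold takes over) and
  this floor is intrinsic to requiring independent bidirectional
  replication, not a tuning artifact.

## Problem sizes used in the package's own checks

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to keep the full suite in minutes: 350-nt founder,
10 generations, 35,000 x 100-nt reads (10,000x) for the sensitivity study;
1-kb control at 50,000 reads x 100 replicates for noise rejection;
14,000 x 50-nt reads (2,000x) for the iterative-rescue study with a
five-SNV cluster at 40% VAF.  These sizes are the package's reference
conditions; all of them scale up linearly in read count.

## Known limitations

* Indels are reduced to missing data (`-`) or dropped; the method does not
  genotype them.
* The built-in mapper is ungapped and single-threaded — a test instrument,
  not a production aligner.
* Fragment-clipped mapping of reads longer than $2L$ biases per-track
  tally composition slightly; choose $L$ to fit the read length.
* The Fisher-test 2x2 construction counts sites, not mutations, and takes
  motif context from the reference allele.
* Verification cannot span the analyzed-span boundaries; the outermost
  half-ROA of each end is effectively unreportable at default eligibility.
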