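Package: wordict
Title: Word-Dictionary Detection of Low-Frequency Variants in Hypermutated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies low-frequency single-nucleotide variants
    (VAF below 1 percent) and tumor subclones in densely mutated genomic
    regions such as immunoglobulin loci under somatic hypermutation. Mapped
    reads are partitioned into two offset tracks of fixed-length regions of
    analysis (ROAs), compressed into per-ROA dictionaries of unique haplotype
    words with per-strand counts, filtered with a coverage-dependent
    bidirectional threshold, and cross-verified by half-word matching against
    dictionaries built from independent read sets. Verified words are
    assembled into alternate reference fragments that drive iterative
    remapping of reads into regions where dense variation defeats ordinary
    alignment. Includes a verified-word variant caller that reports multiple
    alternate bases per site, subclone ranking and phylogeny export, AID
    mutational-motif (WRCY, WA/TW) classification with a one-tailed Fisher
    enrichment test, and a clonal-population read simulator with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
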