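Package: hiddenbreak
Title: Detection of the 28S rRNA Hidden Break from RNA-Seq Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the two conserved 20-mer sequences that flank the
    protostome 'hidden break' of the 28S ribosomal RNA, maps paired-end
    RNA-Seq reads to a 28S reference with a built-in ungapped
    seed-and-extend aligner (or imports external SAM alignments), computes
    per-position read depth, log2 forward/reverse strand ratios and
    spanning-read-pair profiles, and turns the characteristic coverage
    drop between the markers into a reproducible present/absent break
    call. Also provides comparative statistics of the inter-marker region
    (marker distance, AU content, UAAU motif counts, Welch's t-test) for
    cohorts of 28S sequences, and a paired-end read simulator that
    generates libraries from intact or cleaved molecules with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
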