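Package: squigglemap
Title: Real-Time Mapping of Raw Nanopore Signals with Hash-Based Seeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Maps raw nanopore current signals ("squiggles") to a reference
    genome without basecalling. Raw samples are segmented into events with a
    two-window t-statistic detector, normalized event levels are quantized
    adaptively (a high-resolution fine range flanked by coarse ranges) and
    packed into hash seeds, and seeds are matched against a
    frequency-filtered, optionally minimizer-sketched reference index built
    from a k-mer pore model. Matches are chained with a minimap2-style
    gap-penalty dynamic program and a weighted decision statistic stops
    sequencing-time mapping as soon as the evidence is sufficient, as in
    Read Until selective sequencing. Ships a SLOW5 (ASCII) reader/writer, a
    squiggle simulator with ground-truth output, and a pafstats-style
    evaluator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
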