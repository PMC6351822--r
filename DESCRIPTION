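Package: cffrag
Title: Cell-Free DNA Fragmentomics of Aging Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of plasma cell-free DNA (cfDNA) fragment libraries as a
    readout of the nucleosome landscape of dying cells. Implements fragment
    filtering and downsampling, fragment-length profiling, 100-kb bin signals
    annotated with Hi-C subcompartments (median-of-ratios fold changes,
    rank and variance tests, and a Gibbs-sampled random-intercept model with
    credible-interval comparisons), strand-aware metaprofiles around TSS, TTS
    and CTCF anchors, repeat-element consensus coverage with fractional
    multi-map attribution, and window-protection-score (WPS) periodograms for
    tissue-of-origin rank-shift inference. A synthetic cfDNA cohort simulator
    with recorded ground truth makes every stage testable end to end without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
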