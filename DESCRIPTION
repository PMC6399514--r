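Package: bspmeth
Title: Bisulfite Sequencing PCR Analysis of Promoter CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clone-based bisulfite sequencing PCR (BSP) studies of
    promoter methylation: sliding-window CpG-island detection, in-silico
    bisulfite conversion, bisulfite-aware alignment and per-clone methylation
    calling with conversion-efficiency quality control, per-site and integral
    methylation rates with lollipop renderings, weekly phenotype summaries and
    laying-stage segmentation, 2^-ddCt relative expression with compact letter
    displays, Pearson association of methylation with expression and phenotype,
    transcription-factor motif scanning with CpG overlap, and a seeded
    synthetic-study generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
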