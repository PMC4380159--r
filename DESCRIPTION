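Package: spikelin
Title: Spike-In Linearity Benchmarking for RNA-Seq Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates how faithfully RNA-seq library preparation protocols
    recover linear changes in transcript abundance, using two-species
    mixture ("spike-in") designs in which whole RNA from a spike species is
    mixed into a background species at known fractions.  Reads HTSeq-count
    style per-gene count tables, subsamples libraries to equal depth by
    multivariate hypergeometric draws, rescales each gene onto the known
    mixing-fraction axis by a weighted no-intercept normalization, fits
    per-gene linear dose responses and summarizes slope, intercept and
    Pearson correlation distributions per protocol.  Includes an ideal
    protocol null model with pure multinomial counting noise, a
    decomposition of replicate slope variance into intrinsic and extrinsic
    (pre-amplification) components, library molarity and equimolar pooling
    calculations, and a synthetic two-species count generator so the whole
    pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
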