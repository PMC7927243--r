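Package: sortnoise
Title: Sort-Seq Reconstruction of Single-Cell Expression Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-variant single-cell fluorescence distributions
    from Sort-seq experiments, in which a pooled reporter library is sorted by
    FACS into log-spaced fluorescence bins and each bin is sequenced with a
    bin-specific barcode. Read counts per bin are converted to estimated cell
    counts, fitted to a Gamma distribution by interval-censored maximum
    likelihood, and summarised as mean, variance and noise (squared coefficient
    of variation). Includes the quality filters used for such libraries
    (minimum occupied bins, minimum cells per sequence, replicate concordance
    gates), codon-usage scoring of the variable region (CAI, TAI, nTE, GC
    content, mean-centred mRNA folding energies), a virtual-binning simulator
    for choosing the number and spacing of sorting bins, and a ground-truthed
    synthetic data generator covering the full FACS-plus-sequencing process.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    seqinr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
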