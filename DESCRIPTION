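Package: scrleak
Title: Stop Codon Readthrough Detection and Leak-Rate Modelling from
    Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects stop codon readthrough (SCR) events in transcript-space
    ribosome profiling data and models the ribosomal leak rate from the
    stop-codon sequence context. Builds per-nucleotide footprint density
    profiles, estimates the leak rate as the ratio of cumulative density in a
    window downstream of the stop codon to the density at the end of the
    coding region, applies coverage and distance filters, and stratifies
    events into rate sets. Characterises the 70-nt stop-codon context by
    positional Kullback-Leibler divergence, pairwise mutual information,
    Fisher GC-versus-AU tests and GC3 profiles, and fits a minimum-norm
    least-squares linear model (via singular value decomposition) that
    predicts the leak rate from nucleotides at divergence-selected positions.
    Includes a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
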