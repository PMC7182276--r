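Package: flyosn
Title: Odorant Transduction and Spike Encoding in Drosophila Olfactory
    Sensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates fruit fly olfactory sensory neurons as a cascade of an
    odorant transduction process (ligand-receptor binding and dissociation
    kinetics, a peri-receptor low-pass filter, a co-receptor channel with
    fractional-power calcium feedback, and a Hill-type transduction current)
    and a Connor-Stevens biophysical spike generator with Brownian current
    noise. Provides the stimulus waveform families used to characterise such
    neurons (steps, ramps, parabolas, staircases, triangles, band-limited
    white noise), sliding-window peristimulus time histograms, an
    inverse-mapping estimator of odorant-receptor affinity and dissociation
    rates (including receptor-by-odorant affinity matrices from spike-count
    tables), differential-evolution parameter fitting, a ridge estimator of
    the two-dimensional concentration/concentration-gradient encoding
    manifold, and an antenna-level population simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
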