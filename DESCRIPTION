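Package: tacsalpha
Title: After-Effects of Short-Period Alpha-tACS in Simulated
    Electrophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of after-effects of short transcranial
    alternating current stimulation (tACS) trains on alpha-band oscillatory
    power in trial-structured multi-unit recordings. Provides a seeded
    synthetic-data generator with known effect parameters (individual alpha
    peak, stimulation-induced power gain, slow rhythmic amplitude
    modulation, 1/f background noise, spatial unit layouts with adjacency),
    estimation of the individual stimulation frequency (ISF), Hanning-taper
    time-frequency decomposition with ISF-aligned frequency axes,
    baseline-relative delta-power statistics, nonparametric cluster-based
    permutation inference over spatial and time-frequency adjacency,
    trial-order binning with Friedman and Conover rank statistics, and a
    filter-Hilbert modulatory-power spectrum of slow (0.1-2 Hz) rhythmic
    power fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    pracma
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
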