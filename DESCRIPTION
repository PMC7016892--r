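Package: lfposc
Title: Laminar LFP Band Power, Envelope Connectivity and Phase-Amplitude
    Coupling Under Anesthesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel local field potential (LFP)
    recordings from laminar probes spanning cortex and hippocampus under
    anesthesia: physiology-gated selection of stable analysis windows from
    ECG and respiration, zero-phase preprocessing (Gaussian comb notch,
    Butterworth low-pass, running-median baseline removal, decimation),
    Welch band-power profiles with slow-oscillation/delta and Low/High
    imbalance ratios, all-pairs Hilbert-envelope cross-correlation
    connectivity with signed latencies and regional averaging, a general
    linear model phase-amplitude coupling index, and rank-based group
    statistics (Kruskal-Wallis with Sidak-adjusted gatekeeping,
    Mann-Whitney). Includes a synthetic multichannel LFP and physiology
    generator with fully known ground truth (band power fractions,
    inter-channel slow-oscillation lags, coupling depths, unstable
    physiology epochs) so that every stage is verifiable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
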