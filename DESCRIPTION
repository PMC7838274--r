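Package: fibsir
Title: Frequency-Independent Biological Signal Identification and Network
    Analysis for Calcium Imaging and Synaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event detection for slow calcium-fluorescence traces and fast
    voltage-clamp current recordings using running-median baselines, traced
    trough/peak reference lines and Ramer-Douglas-Peucker waveform
    simplification (the FIBSI approach), together with the downstream
    analyses built on it: per-neuron event summaries and silent-cell
    classification, amplitude-cutoff filtering, normalized-amplitude
    histograms, drug fold-change grouping, Pearson/Fisher-Z network
    synchrony, spontaneous-EPSC quantification with charge transfer and
    k-medoids clustering with silhouette-based model selection, and the
    accompanying statistical battery (Fisher exact, Brown-Forsythe and
    Welch ANOVA with Games-Howell, Kruskal-Wallis with Dunn, paired and
    repeated-measures comparisons with Sidak adjustment). Includes
    synthetic-data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
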