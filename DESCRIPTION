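Package: arquant
Title: Detection and Quantification of Asynchronous Quantal Release in
    Evoked Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect delayed quantal events in stimulus-evoked
    voltage-clamp sweeps and quantify asynchronous neurotransmitter release
    (AR). Implements synchronous-EPSC measurement and bi-exponential decay
    subtraction, filtered-derivative threshold event detection with
    synapse-specific presets, spontaneous-corrected AR rates and
    peristimulus time histograms with exponential time-course fits, and
    genotype-level statistical comparison. A synthetic sweep generator with
    full ground truth makes the whole pipeline verifiable by parameter
    recovery, and a companion module implements a binned co-detection
    analysis of single-nucleus RNA-seq transcript counts with a binomial
    transcript-dropout null model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
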