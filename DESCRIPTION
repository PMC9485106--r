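Package: fearlfp
Title: Trial-Aligned LFP Band Power and Inter-Region Theta Coupling for
    Fear-Conditioning Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-region local field potential (LFP)
    recordings collected during a five-day discriminative auditory fear
    conditioning protocol. Provides linear-phase FIR band decomposition into
    theta (4-10 Hz), slow gamma (30-55 Hz) and fast gamma (55-100 Hz) bands,
    Welch power spectral density of 15-s conditioned-stimulus and pre-stimulus
    windows, normalized CS-evoked power ratios averaged over session blocks,
    and prelimbic-infralimbic functional coupling via the peak normalized
    cross-correlation coefficient. A synthetic-data module generates complete
    two-region datasets (1/f background, band-limited oscillations,
    multiplicative CS-evoked gains, lagged shared theta components) with known
    ground truth, so every stage of the pipeline is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
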