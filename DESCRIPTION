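Package: oscdyn
Title: Noise-Free Prestimulus EEG Oscillations and Their Links to ERPs and Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for within-task EEG brain dynamics
    in an equiprobable auditory Go/No-Go paradigm. Generates multichannel EEG
    sessions with known pink-noise, white-noise, oscillation, ERP, and coupling
    ground truth; preprocesses and epochs recordings with rule-based artifact
    rejection; derives prestimulus amplitude spectra; fits a constrained
    pink + white noise model whose oscillation residuals are guaranteed
    non-negative and subtracts it to obtain noise-free oscillation spectra;
    decomposes oscillation spectra (frequency PCA, Promax) and Go/No-Go ERPs
    (temporal PCA, Varimax); summarises behaviour; and links prestimulus
    measures to ERP components and behaviour by stepwise multiple regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
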