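Package: crcscreen
Title: Multistate Simulation of Colorectal Cancer Screening with Gateopener FIT Pretesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time multistate (Markov) simulation of colorectal cancer
    natural history (adenoma-carcinoma sequence) and of colonoscopy-based
    screening strategies, including conventional screening colonoscopy,
    conventional biennial fecal immunochemical testing (FIT), and 'gateopener'
    screening in which a single low-threshold FIT every ten years pre-selects
    participants for colonoscopy. Ships the diagnostic characteristics of a
    quantitative FIT at multiple hemoglobin cut-offs, decomposes them into
    state-conditional positivity profiles, calibrates a synthetic quantitative
    hemoglobin cohort generator against them, and computes prevented cases and
    deaths, resource use, and efficiency ratios across scenario grids with
    adherence and drop-out dynamics and parameter-uncertainty sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
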