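Package: esccsim
Title: Natural-History Simulation, Calibration and Screening Evaluation for
    Esophageal Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (semi-Markov) model of the natural
    history of esophageal squamous cell carcinoma (ESCC) in high-risk regions:
    thirteen health states from normal mucosa through ordered precancerous
    lesions (basal cell hyperplasia/mild, moderate and severe dysplasia) to
    undetected and detected TNM stage I-IV cancer and death, with an
    age-dependent piecewise log-linear onset hazard and a duration-dependent
    lesion progression hazard tracked by annual tunnel compartments.  Includes
    a likelihood-based calibration engine (binomial goodness-of-fit against
    age-specific prevalence, incidence and stage-at-diagnosis targets, genetic
    algorithm search, sampling importance resampling for posterior
    uncertainty) and a screening-scenario layer that evaluates one-time
    endoscopic screening with imperfect sensitivity, regional risk
    adjustment, and trial-style cumulative-incidence and hazard-ratio
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
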