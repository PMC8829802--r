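Package: perfcon
Title: Simulation and Concordance Analysis of PET and ASL Cerebral Perfusion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing agreement between cerebral blood flow (CBF)
    maps from dynamic oxygen-15 water PET and pseudo-continuous arterial spin
    labeling (pCASL) MRI. Includes a digital brain phantom simulator with
    ground-truth perfusion, arterial transit time and focal hypoperfused
    lesions; one-tissue-compartment dynamic PET simulation and non-invasive
    CBF quantification calibrated by phase-contrast MRI whole-brain flow;
    single-delay and Hadamard time-encoded pCASL signal simulation, decoding
    and kinetic quantification with transit-time fitting; single-case
    hypoperfusion mapping with Crawford-Howell modified t-tests and
    cluster-extent thresholds; and binary-mask and ROI-level concordance
    metrics (sensitivity/specificity, overlap partition, Jaccard, regression,
    Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
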