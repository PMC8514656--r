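Package: cardamis
Title: Annealed Adaptive Multiple Importance Sampling for Regional
    Cardiac Tissue Parameter Inference from Deformation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian estimation of regional ventricular tissue properties
    (contractility, stiffness, activation timing, wall size) from segmental
    longitudinal strain traces and global measures (ejection fraction,
    end-diastolic volume, right-ventricular basal diameter) using annealed
    adaptive multiple importance sampling (AMIS).  Includes a self-contained
    surrogate multi-segment ventricular mechanics model behind a pluggable
    forward-model interface, a strain/strain-rate/inter-segmental likelihood,
    derived tissue-property posteriors, and validation statistics
    (overlap-over-union mutual information, highest-density-interval
    trueness, weighted posterior correlation matrices), plus virtual-patient
    generation for in silico validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
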