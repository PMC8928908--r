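Package: occuCorr
Title: Single-Season Occupancy Models with Spatially Correlated Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Site-occupancy models for detection/non-detection data collected
    on contiguous spatial replicates (transect segments), where local presence
    of sign follows a first-order Markov chain along the transect. Provides
    maximum-likelihood estimation for the standard single-season occupancy
    model and the correlated-detection model, covariate modelling on occupancy
    and detection through logit links, AIC ranking with Akaike weights, a
    two-step detection-then-occupancy model selection strategy with stepwise
    additive covariate search, AIC-weighted model averaging with unconditional
    standard errors, and parametric-bootstrap goodness-of-fit with an
    overdispersion factor. Includes a seeded simulator for detection histories
    with latent truth recorded, for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
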