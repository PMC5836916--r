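Package: bloodwalk
Title: Monte-Carlo Simulation and Analysis of Water Diffusion in Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte-Carlo random-walk simulation of water diffusion in a
    two-compartment model of blood (plasma and red blood cells with
    permeable membranes), under monopolar and flow-compensated
    diffusion-gradient profiles. Computes apparent diffusion coefficient
    (ADC) and apparent diffusional kurtosis from diffusion-encoded phase
    distributions as functions of hematocrit and diffusion time. Also
    provides the companion measurement-analysis chain: sum-of-squares
    noise-floor correction, SNR-based exclusion, three-b-value ADC and
    mono-exponential T2 fitting, blood-count correlation and regression,
    and blood-count based calibration of the blood diffusion coefficient
    for intravoxel incoherent motion (IVIM) modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
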