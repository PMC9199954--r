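Package: nirsperf
Title: Performance Assessment of Time-Domain Diffuse Optics Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual-instrument implementation of the standard multi-laboratory
    performance-assessment protocols for time-domain near-infrared spectroscopy
    (TD-NIRS) and related diffuse-optics instrumentation. Provides an analytic
    diffusion-theory forward model for time-resolved reflectance and
    transmittance with first-order (Born) perturbation by a small absorbing
    inclusion; a virtual TCSPC instrument and virtual phantom kits that
    synthesize distributions of times of flight (DTOFs) with realistic
    instrument response functions, Poisson counting noise, dark counts,
    differential nonlinearity, drift and session-to-session variability;
    retrieval of absorption and reduced scattering coefficients by fitting the
    IRF-convolved diffusion model; and the basic-instrument-performance,
    optical-property (accuracy, linearity, crosstalk, stability, noise,
    reproducibility) and inhomogeneity-detection (time-windowed contrast and
    contrast-to-noise ratio over a depth scan) figures of merit, together with
    summary-statistics reporting and a virtual measurement-campaign driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
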