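Package: drspipe
Title: Diffuse Reflectance Spectroscopy Pipeline for Colorectal Tissue
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing broadband diffuse reflectance spectra
    (350-1920 nm) of colorectal mucosa and tumor tissue: reflectance
    computation from raw spectrometer intensities, merging of
    visible/NIR and NIR/SWIR spectrometer readings over their overlap
    region, per-wavelength statistical band selection (normality-gated
    t-test with Wilcoxon fallback), partial least squares feature
    extraction followed by weighted k-nearest-neighbor classification
    under a repeated two-fold cross-validation protocol, and
    chromophore/scattering attribution of PLS loadings. Includes a
    physics-based synthetic spectra generator (diffusion-approximation
    forward model over hemoglobin, water and lipid absorption) that
    emulates the hierarchical patient/site structure of clinical
    datasets so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
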