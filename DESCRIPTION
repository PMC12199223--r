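Package: ramanpws
Title: Hybrid Raman and Partial Wave Spectroscopy Analysis of Field
    Cancerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for hybrid Raman spectroscopy
    (RS) and partial wave spectroscopy (PWS) measurements of tissue
    fields of view, aimed at detecting field cancerization in
    normal-appearing tissue adjacent to premalignant lesions. Provides
    Raman spectral preprocessing (Savitzky-Golay smoothing, iterative
    modified multi-polynomial (iModPoly) fluorescence baseline removal,
    region cropping, vector normalization, DBSCAN outlier screening),
    PWS spectral-fluctuation imaging with gray-level co-occurrence
    matrix (GLCM) texture quantification via the inverse difference
    moment (IDM), marker-band Mann-Whitney statistics, and multimodal
    data fusion with PLS-DA classification under stratified k-fold
    cross-validation and one-standard-error component selection. A
    synthetic two-group cohort generator emulates the acquisition
    design (10 x 10 Raman grids per FOV, 151-wavelength PWS stacks) so
    the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
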