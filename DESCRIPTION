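Package: libsquant
Title: Quantitative Laser-Induced Breakdown Spectroscopy Calibration for
    Heavy Metals in Herbal Material
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration pipeline for quantifying heavy metals (Cd, Cu, Pb)
    in powdered herbal material from laser-induced breakdown spectroscopy
    (LIBS) spectra. Provides a synthetic LIBS spectrum generator emulating a
    spiked concentration-gradient study design (8 brands x 8 gradient groups
    x 3 replicates, 1024 channels over 210-231 nm), spectral pretreatments
    (multiplicative scatter correction, standard normal variate, wavelet
    denoising, Savitzky-Golay smoothing) with cross-validated selection,
    wavelength selection by principal component analysis, the successive
    projections algorithm (SPA) and competitive adaptive reweighted sampling
    (CARS), partial least squares regression and back-propagation neural
    network regressors, hybrid networks whose initial weights are optimized
    by particle swarm optimization (PSO-BP) or the sparrow search algorithm
    (SSA-BP), and an evaluation suite (R2, RMSEC/RMSECV/RMSEP, RPD) with a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
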