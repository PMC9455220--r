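Package: biosas
Title: Small-Angle X-Ray Scattering Analysis Pipelines for Biological Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline, reproducible analysis of biological small-angle X-ray
    scattering (BioSAXS) data. Provides Guinier-region fitting by three
    algorithms (window search, consensus, Guinier-peak analysis), a Bayesian
    indirect Fourier transform (BIFT) for the pair-distance distribution
    function, the correlation-map (CorMap) frame-equivalence test with its
    exact longest-run null distribution, Porod and Rambo-Tainer invariants,
    diode-weighted detector-frame reduction with Poisson uncertainty
    propagation, and the sample-changer and SEC-SAXS (inline chromatography)
    pipelines, including SVD/NMF chromatogram decomposition. A synthetic-data
    generator with known ground truth (sphere and Gaussian-chain form factors,
    Poisson counting noise, simulated detector frames and elution runs) makes
    every stage testable without beamline data. Results are written to HDF5
    bundles and three-column ASCII files; pipelines replay deterministically
    from JSON job descriptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    minpack.lm,
    stats,
    utils,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
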