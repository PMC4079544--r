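Package: soakfit
Title: Crystal-Size-Dependent Ligand Soaking Models and Electron-Counting
    Occupancy Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models how ligand occupancy in soaked protein crystals depends
    on crystal size and soak time. Provides the hyperbolic saturation model
    with a size-proportional half-time (t_1/2 = L*tau), least-squares
    estimation of its parameters with goodness-of-fit and residual
    diagnostics, intra-crystalline dissociation constants from the fraction
    saturation equation, a seeded generator of synthetic soak-experiment
    tables, a small crystallographic sandbox (Gaussian-atom structures,
    absolute-scale density maps, Fourier structure factors, CCP4/MRC map
    input and output), and an absolute-scale electron-counting estimator of
    ligand occupancy with displaced-water correction and three-model
    consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
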