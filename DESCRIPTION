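Package: geldiff
Title: Degradation-Release and Diffusion Modelling of Autofluorescent Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the in vivo fate of fluorophores released from a degrading
    subcutaneous hydrogel depot as tracked by whole-animal fluorescence imaging.
    A Weibull-in-time, disk-in-space release source drives an axisymmetric
    diffusion equation with an apparent constant diffusivity; the package
    evaluates the analytical Hankel-transform solution, cross-checks it against
    an independent Crank-Nicolson finite-difference solver with mass-balance
    audits, generates synthetic fluorescence image stacks with seeded noise,
    extracts radial intensity profiles by azimuthal averaging, and estimates
    the apparent diffusivity from radial intensity time series by bounded
    nonlinear least squares with residual-bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    pracma,
    minpack.lm,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
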