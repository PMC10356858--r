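Package: lasertherm
Title: Treatment Planning for Laser Thermal Pain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans laser-evoked thermal pain stimulation of human skin under
    operating-parameter uncertainty. Provides a layered axisymmetric Pennes
    bioheat finite-volume solver with a Gaussian Beer-Lambert volumetric laser
    source; design-of-experiments tools (optimal Latin hypercube sampling,
    the L9(3^4) orthogonal array with range and variance analysis, single-factor
    sweeps); a Gaussian radial-basis-function network surrogate for the two
    treatment indicators (thermal penetration at 20 um depth and skin surface
    temperature); and nonlinear interval-uncertainty optimization using the
    reliability-based possibility degree of interval (RPDI), solved with a
    nested real-coded genetic algorithm over interval midpoints and a
    multi-start local inner bound search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
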