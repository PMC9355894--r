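Package: iphase
Title: Depth Independence of Inelastic Phase Contrast in Energy-Filtered TEM
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulation of elastic and plasmon energy-loss
    scattering of 300 keV electrons through a layered Pt/Al/C specimen,
    with energy-loss filtering and three event-sequence scenarios for when
    phase contrast is formed, together with a closed-form oracle for the
    same acceptance probabilities. Also provides a synthetic generator of
    energy-filtered defocus series of lattice-fringe particles with Poisson
    shot noise, and the full measurement pipeline: series alignment,
    particle boxing, lattice-reflection power from the Fourier transform,
    squared-fluence normalization, series maxima, ensemble statistics,
    Student's t-test, top/bottom ratio with propagated uncertainty, and
    sigma-exclusion statistics against simulated scenario ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
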