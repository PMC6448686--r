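Package: fibrilsas
Title: Small-Angle Scattering Analysis of Cellulose Microfibril Nanostructure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-based analysis of equatorial small-angle X-ray and neutron
    scattering (SAXS/SANS) data from wood and other cellulosic materials. The
    core intensity model describes cellulose microfibrils as polydisperse,
    infinitely long cylinders packed on a hexagonal lattice with
    paracrystalline distortion of the second kind, plus a low-q power law for
    pore surfaces and an optional Gaussian term centred at q = 0. The package
    also provides the reduction of fibre-symmetric 2D detector patterns into
    background-separated equatorial 1D curves, a weighted bounded
    least-squares fitting engine with fixed-parameter recipes and a
    drying-series mode, equatorial WAXS peak fitting with Scherrer crystal
    sizes, and seeded synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
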