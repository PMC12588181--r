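Package: jawforce
Title: Static-Equilibrium Bite-Force Modelling of the Mammalian Masticatory Apparatus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maximum bite force from dissection-based muscle
    architecture (mass, fibre length) and jaw landmark geometry using a
    static-equilibrium lever model of the mandible. Computes physiological
    cross-sectional areas and maximum muscle force vectors, projects them
    into the sagittal plane, balances moments about the condyle to obtain
    the bilateral bite force at arbitrary bite points, sweeps the gape
    angle by rigid rotation of the mandible to locate the optimal gape,
    calibrates muscle stress (specific tension) against in vivo bite
    forces, and runs one-at-a-time parameter sensitivity analyses.
    Includes a seeded synthetic-geometry generator for testing and an
    example dataset from two Marmosa murina specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
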