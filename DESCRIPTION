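Package: lipotrack
Title: Single-Particle Liposome Sizing, Curvature-Preference and
    Vesiculation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nanoparticle-tracking-style analysis of liposome populations.
    Converts Brownian trajectories of single particles into hydrodynamic
    diameters via lag-1 mean-squared-displacement estimation and the
    Stokes-Einstein relation, bins the results into 5-nm concentration
    distributions, and implements two membrane-biology assays on top: a
    curvature-preference classification that compares the size distribution
    of a fluorescent protein-bound liposome subpopulation against the total
    population, and a vesiculation dose-response readout based on the
    concentration of small vesicles. Includes a seeded physics simulator
    (extruded lognormal liposome populations, curvature-dependent binding,
    size-dependent diffraction detectability, Brownian 2D tracks,
    area-conserving vesiculation) so the full pipeline can be exercised and
    tested without an instrument, plus CSV import/export mimicking tracking
    software output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
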