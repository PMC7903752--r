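Package: lumenosc
Title: Mechanics and Multiscale Analysis of Epithelial Organoid Size Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inflation-rupture size oscillations of single-layer
    spherical epithelial organoids. Provides a mechanical 3D agent-based simulator of
    an osmotically inflated cell monolayer (spring, pressure and bending forces,
    stochastic overdamped dynamics, cell division, rupture and resealing of the
    shell), the analytic osmotic scaling law relating surface growth to luminal
    pressure, mesoscale feature extraction from projected-area time series
    (decline/expansion phases, oscillation events, expansion factors, circularity),
    point-cloud morphometry on nuclei centroids (Delaunay and proximity cell graphs,
    hull volume/surface, centroid-matching F score), and seeded synthetic-data
    generators for every input shape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    interp,
    quadprog,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
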