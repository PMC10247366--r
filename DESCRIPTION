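Package: clusterkit
Title: Membrane Curvature, Vesiculation Kinetics and Single-Molecule
    Cluster Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of membrane remodelling by curvature-active
    proteins and of their nanoscale clustering. Provides least-squares sphere
    fits and Monge-representation curvature fields for coarse-grained membrane
    point clouds, bicelle-to-vesicle transition classification and
    shifted-exponential (Poisson-with-lag) waiting-time kinetics with
    acceleration factors, single-linkage protein cluster tracking with
    ubiquitin contact and membrane-budding metrics, and a DNA-PAINT /
    qPAINT toolchain: localization quality control, NeNa precision,
    trace linking, fiducial removal, DBSCAN nanocluster detection,
    Voronoi first-rank-density microcluster segmentation, log-normal mode
    estimation and dark-time copy-number inference. Seeded synthetic-data
    generators emulate every input so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
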