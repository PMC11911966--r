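Package: seasonstruct
Title: Seasonal Structural Stability of Forest Canopies from UAV-LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to link remotely sensed forest structural metrics and
    their seasonal stability to tree diversity, variability, and the net
    biodiversity effect (overyielding) in tree diversity experiments.
    Includes a synthetic forest-scene generator (species pool, experimental
    design, annual inventories, per-survey point clouds with phenology),
    a point-cloud conditioning chain (height normalization, plot clipping,
    statistical outlier removal, voxel decimation), per-plot structural
    metrics (canopy height heterogeneity, fractional cover, and a
    Hill-diversity box-counting fractal dimension), inverse-CV seasonal
    stability, wood-volume productivity with the Loreau-Hector
    complementarity/selection partition of the net biodiversity effect,
    Hill diversity and Helmus-type variability on phylogenetic, functional
    and taxonomic trees, and a statistical layer of cross-sectional
    regressions, mixed models and structural equation models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    FNN,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    picante,
    vegan,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
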