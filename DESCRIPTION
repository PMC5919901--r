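Package: paleobrain
Title: Reconstruction of Fossil Hominin Brains from Endocasts by
    Diffeomorphic Deformation of a Population-Average Brain
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational-anatomy toolkit for estimating brain morphology
    from endocranial casts. Builds population-average endocast and brain
    templates by DARTEL-style diffeomorphic registration (stationary
    velocity fields, scaling-and-squaring, mean-squared-difference matching
    with a linear-elastic penalty), restores damaged endocasts by
    thin-plate-spline landmark warping, deforms the average brain and an
    AAL-style parcellation into each endocast to measure regional volumes,
    and provides the downstream statistics: vertex-wise Hotelling T-squared
    surface morphometry with permutation family-wise-error control,
    ICV-adjusted regional volumetrics with Ryan's pairwise procedure,
    cerebellar laterality analysis on symmetrized atlases, and
    confound-adjusted cognition regressions. A synthetic phantom-cohort
    generator with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
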