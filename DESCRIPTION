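Package: rodentmorph
Title: Morphometry of Rodent Knee Ligaments and Menisci from Segmented 3D Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the geometry of rodent (rat and mouse) knee soft
    tissues from segmented 3D surfaces exported from high-field MRI. Reads and
    writes STL surface meshes and binary label volumes, aligns ligaments to
    their longitudinal axis by principal components, slices them in fixed
    increments to build cross-sectional-area (CSA) profiles, and summarizes the
    midsubstance CSA with optional normalization to tibial plateau footprint
    area. Measures meniscal widths and heights at anterior-horn, central and
    posterior-horn regions from anatomically oriented meshes. Includes the
    accompanying statistical stage (Kruskal-Wallis with post hoc tests,
    aligned-rank-transform two-way factorial analysis, Bonferroni correction,
    intraclass correlation and Bland-Altman agreement analysis) and a synthetic
    phantom generator with analytic ground truth so every pipeline stage is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
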