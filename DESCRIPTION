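Package: mycomorph
Title: Morphometry and Metabolite Statistics for Microparticle-Enhanced
    Cultivations of Filamentous Microbes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphology and replicate statistics for
    submerged cultivations of filamentous microorganisms such as
    Streptomyces rimosus, with or without inert microparticles (talc).
    Segments phase-contrast-like grayscale micrographs (median filter,
    Sobel edge refinement, automatic bimodal threshold, 8-connected
    labeling), computes per-object shape descriptors (projected area,
    elongation, solidity/roughness, maximum Feret diameter) and the
    dimensionless morphology number Mo = 2*sqrt(A)*S/(sqrt(pi)*D*E),
    classifies objects into spores, pellets and clumps/hyphae, and
    summarises groups with confidence bands. Computes secondary-metabolite
    enhancement factors with Welch t-tests, and volumetric glucose uptake
    rates by differentiating cubic spline fits of concentration curves.
    Includes a seeded synthetic-data generator (images with per-object
    ground truth; replicate culture time series with known effect sizes)
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    tiff,
    png,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
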