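Package: canophot
Title: Multiscale Canopy Photosynthesis with Ray-Traced Light and Nitrogen Acclimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parametric 3D cereal canopies as triangle meshes, traces their
    diurnal photosynthetically active light environment with a forward Monte-Carlo
    ray tracer, distributes leaf nitrogen down the canopy from the light profile,
    optimizes each leaf's nitrogen partitioning among photosynthetic protein pools
    (photo-acclimation), and integrates a mechanistic leaf photosynthesis model to
    daily canopy CO2 uptake and nitrogen use efficiency. Includes chlorophyll
    bookkeeping between photosystem antenna size and leaf optical properties, and a
    scenario engine for evaluating reduced-chlorophyll (truncated antenna) canopies
    under different architectures and latitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
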