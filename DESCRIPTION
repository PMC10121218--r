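Package: plumevol
Title: Perceptual Color Spaces, Plumage Complexity, and Phylogenetic
    Rates of Plumage Color Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of plumage coloration across
    a phylogeny: a receptor-noise-limited avian visual model turning
    reflectance spectra into perceptually uniform chromatic coordinates
    (Euclidean distance = just-noticeable difference) and luminance JND
    values; intraspecific plumage-complexity metrics (mean interpatch
    distance, colorspace convex-hull volume or lightness range, and the
    number of contiguous perceptually uniform plumage regions on a patch
    adjacency graph); multivariate Brownian-motion rate estimation with
    group rate-ratio permutation tests; Pagel's lambda fitting,
    phylogenetic PCA and multivariate phylogenetic signal; univariate
    PGLS with stepwise AIC and VIF diagnostics; distance-based PGLS with
    residual randomization; two-block phylogenetic partial least squares
    integration; taxonomic variance partitioning; and a synthetic-data
    generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
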