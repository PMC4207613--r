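Package: meioquant
Title: Quantitative Cytology of Meiotic Crossover Maturation in C. elegans Germlines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the probability that a cytologically designated
    crossover site (a COSA-1 focus) matures into a chiasma, by fitting a
    binomial thinning model that links per-nucleus COSA-1 focus counts to
    chiasma counts inferred from DAPI-stained body counts at diakinesis.
    Also provides the supporting germline quantitation toolkit: zone-based
    homolog pairing profiles with per-gonad dispersion and zone-wise t
    tests, semi-automated 3D fluorescence focus counting with nucleus
    segmentation and a convex-hull containment constraint, per-zone
    rank-sum comparisons of focus counts, Fisher's exact test for double
    crossover-designation events, meiotic-progression extents under a
    majority-per-column rule, and a seeded synthetic-gonad generator
    (count tables and rendered image stacks with full ground truth) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    tiff,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
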