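Package: knotrelax
Title: Topological Relaxation of Knotted Ring Polymers with a Mobile
    Strand-Crossing Segment
Version: 0.1.0
Authors@R:
    person("knotrelax", "developers", email = "knotrelax@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained simulation and analysis of type-II
    topoisomerase mediated unknotting of DNA rings. Provides a bead-spring
    semiflexible ring-polymer Langevin engine with a designated soft
    (strand-crossing) segment, five segment-relocation models (static,
    random jump, curvilinear diffusion, jump to maximum local curvature,
    jump to maximum local density), a knot toolkit (KMT chain reduction,
    Alexander determinant at -1, shortest physically-knotted-arc
    localisation via minimally interfering closure), ensemble topological
    observables (knotting probability with blocking-method errors,
    topology-change rate, maximum knot determinant, exponential decay
    fits, physical unit mapping), and an idealised two-dimensional
    random-walk model of knot-space sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
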