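Package: chromhet
Title: Conformational Heterogeneity of 3D Chromatin Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cell-to-cell conformational heterogeneity of 3D genome
    organization from ensembles of single-cell chromatin bead-chain models.
    Computes per-cell average inter-locus distance curves <Rs>(s), the
    Conformational Heterogeneity (C.H.) metric and its dimensionless Relative
    C.H. form, with replicate-subsampling error bars and power-law scaling
    exponent fits. Includes the MC-TAD lattice-path algorithm for enumerating
    permissible chromatin paths through N x N x N-bin cubes representing
    topologically associating domains (TADs), the derived intra-TAD spread
    sigma and its physical conversion, a statistical resolution up-conversion
    procedure, and baseline ensemble generators (freely jointed chains,
    orientation-random space-filling curves, tunable-heterogeneity synthetic
    ensembles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
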