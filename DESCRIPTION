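Package: dsbfrag
Title: DNA Double-Strand Break Quantification from Fragment-Length Distributions
Version: 0.1.0
Author: dsbfrag developers
Maintainer: dsbfrag developers <dsbfrag@example.org>
Description: Analysis of DNA double-strand break (DSB) induction from
    individually measured fragment lengths, as produced by atomic force
    microscopy contour measurement of irradiated plasmid DNA. Provides
    fragment-size distribution binning, molecule counting by total-length
    conservation, DSB per DNA molecule and per broken molecule, spatial DSB
    profiles, relative biological effectiveness (RBE) against a Co-60
    reference with quadrature error propagation, analytic expectations under
    the uniform random-breakage null on a circular plasmid, a clustering
    index for the short-fragment excess typical of high-LET radiation, and a
    seeded breakage simulator (Poisson-uniform and track-clustered) that
    emulates AFM fragment-length measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
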