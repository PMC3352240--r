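Package: hebbsort
Title: Spike Sorting with a Stream-Based Hebbian Eigenfilter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete extracellular spike-sorting pipeline (nonlinear
    energy operator detection, peak alignment, principal-component feature
    extraction, k-means clustering) built around a stream-based Hebbian
    eigenfilter: a single-pass generalized Hebbian algorithm (Sanger's
    rule) that learns the leading principal components of aligned spike
    waveforms without covariance computation, eigendecomposition, or a
    spike buffer. Includes a synthetic extracellular recording generator
    with ground truth, a conventional batch PCA oracle for comparison,
    per-neuron true/false positive rate metrics, and analytic
    operation-count and memory models for the streaming and conventional
    algorithms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
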