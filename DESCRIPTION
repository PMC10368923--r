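Package: corticocereb
Title: Cortico-Cerebellar Theta Dynamics from Simulated High-Density EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source-level analysis of cortico-cerebellar theta-band dynamics
    during social interaction, built around a fully synthetic high-density EEG
    generator with known ground truth. Provides an analytic spherical forward
    model with labelled cortical and cerebellar source nodes, FIR band-pass
    filtering and average-reference projection, peak-to-peak epoch rejection
    and repair, shrinkage noise covariance, eLORETA and minimum-norm inverse
    operators, Welch cross-spectra with coherence, symmetric orthogonalization
    and the weighted phase lag index, Z-scored condition contrasts, and
    cluster-based permutation statistics with threshold-free cluster
    enhancement and FDR-corrected region-pair tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
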