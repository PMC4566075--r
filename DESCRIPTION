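Package: gliawave
Title: Analysis of Glial Calcium and Glutamate Signals During Retinal Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-photon fluorescence recordings of
    Muller glial cells in the developing retina together with simultaneous
    voltage-clamp recordings from retinal ganglion cells. The package
    segments regions of interest from fluorescence movies with a
    Laplacian-of-Gaussian filter, computes per-ROI dF/F traces, detects
    fluorescence transients with a derivative-threshold rule, identifies
    retinal-wave epochs from compound excitatory postsynaptic currents,
    and summarises per-wave glial participation, inter-transient-interval
    distributions and evoked-response averages. A seeded synthetic
    experiment generator produces movies, current traces and ground truth
    with the statistical structure the analysis assumes, so the whole
    pipeline can be exercised and validated without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
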