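Package: fmcell
Title: Frequency-Modulation Emulation of Action Potentials and Excitable Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Emulates cardiac and neuronal action potentials with a single
    frequency-modulated sine generator. A phase profile is extracted from any
    uniformly sampled action-potential trace by branch-corrected arcsine
    inversion, converted to a frequency-modulating factor, and compressed into
    a continuous piecewise-linear form by segmented least squares with free
    breakpoints ('pwl_fit'). Fitted profiles reconstruct the action potential,
    can be parameterized against a blockade covariate through piecewise-linear
    fit-type equations, and drive a two-state playback controller that couples
    cells through a discrete diffusion operator into 1-D and 2-D excitable
    tissues with wavefront-timing metrics, minimum-coupling search and lesion
    experiments. Reference FitzHugh-Nagumo and Fenton-Karma models supply
    ground-truth traces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
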