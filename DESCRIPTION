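Package: tifret
Title: Time-Integrated and Lifetime-Based FRET Analysis for TCSPC Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating Forster resonance energy transfer (FRET)
    efficiencies from time-correlated single photon counting (TCSPC)
    fluorescence lifetime image stacks.  Implements classical FLIM-FRET
    (one- and two-exponential tail fits of per-pixel decay histograms) and
    time-integrated FRET (tiFRET), which computes the efficiency from the
    area under the decay curve divided by its amplitude without choosing a
    number of exponential components.  Includes the FRET-spectrometry
    post-processing chain (moving-square ROI segmentation, per-segment
    histogram peaks, meta-histograms, single-Gaussian fits, and
    inverse-variance weighted combination across experiments), the kinetic
    theory of FRET in oligomers (rate additivity, apparent efficiencies,
    lifetime multisets, tetramer configuration enumeration), a TCSPC
    simulator with Poisson counting noise and optional acceptor
    photobleaching, file I/O for time-as-pages TIFF stacks, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
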