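Package: mitoncx
Title: Mode Switching of the Mitochondrial Na+-Ca2+ Exchanger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates matrix free calcium dynamics in a single well-mixed
    mitochondrion whose only inner-membrane calcium transporter is an
    electrogenic Na+-Ca2+ exchanger (NCLX-like). Provides a thermodynamically
    consistent single-exchanger flux law with a closed-form reversal point, an
    ODE driver fed by prescribed cytosolic calcium traces, a generator of
    agonist-evoked oscillating drive traces with receptor desensitisation and
    fura-2-style logarithmic ratio rescaling, and oscillation metrics (peak
    detection, 200-s bin counts, amplitude by oscillation number, washout
    decay half-times, forward/reverse mode segmentation). Includes presets for
    the depolarised-mitochondrion scenarios in which transitions between
    reverse and forward transport modes generate repetitive matrix calcium
    oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
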