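Package: detachmon
Title: Cell Detachment Monitoring from Lens-Free Imaging Time-Lapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies enzymatic cell detachment from reconstructed lens-free
    imaging (phase, intensity) image pairs. A random-forest pixel classifier
    with a multi-scale filter bank segments cells in the phase image; a
    mask-algebra pipeline (thresholding, hole filling, seeded disk dilation,
    small-region reassignment) extracts detached cell regions; the percentage
    of detached cell regions is profiled over a harvesting time-lapse and a
    fixed-threshold rule determines the optimal enzyme-inhibition time. A
    seeded synthetic generator of paired phase/intensity frames with
    pixel-level ground truth and biphasic detachment kinetics makes the whole
    pipeline testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    igraph,
    tiff,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
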