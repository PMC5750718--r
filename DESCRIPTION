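Package: neurocensus
Title: Neuron Counts Along the Primate Early Visual Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of retinal ganglion cells, lateral geniculate
    nucleus (LGN) neurons, and task-relevant primary visual cortex (V1) neurons
    activated by a visual stimulus of given size and eccentricity in the macaque.
    Combines closed-form cortical magnification and LGN cell-magnification
    functions of eccentricity with linear interpolation of retinal ganglion cell
    densities, laminar depth, excitatory and tuned-neuron fractions, and cortical
    neuron density to produce per-stage counts, upper and lower bounds on the V1
    count, and LGN:V1 and RGC:V1 expansion ratios. Every anatomical assumption is
    an explicit parameter; a sensitivity module sweeps any parameter over a grid,
    and a command-line script renders full reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
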