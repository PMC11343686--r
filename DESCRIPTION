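Package: grcltd
Title: Granule-Cell Temporal Bases and Climbing-Fiber-Driven Plasticity Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous cerebellar granule-cell (GrC)
    and climbing-fiber (CF) calcium-imaging sessions recorded during a delayed
    reward reaching task. Converts raw fluorescence into noise-normalized
    traces and inferred CF spike trains, detects reaches and licks from 200 Hz
    behavioral streams, builds trial-aligned tensors and window-based response
    classifications, simulates climbing-fiber-driven long-term depression
    (LTD, with an LTP extension and shuffle/reorder/uniform controls) to
    predict GrC to Purkinje-cell synaptic weights, and evaluates LTD-weighted
    population readouts and cross-validated linear decoding of elapsed time.
    Includes a ground-truth synthetic session generator emulating the
    statistical structure of such recordings so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
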