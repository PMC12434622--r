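Package: osmosys
Title: Unified van 't Hoff Calculations for Osmosis Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse calculations under a unified, membrane-aware
    form of van 't Hoff's law. Computes total-solute-particle concentration
    (ideal and osmotic-coefficient-corrected), the membrane-dependent initial
    osmotic concentration of simple osmosis systems, osmotic pressures and
    pressure gradients of composite systems, and the decomposition of complex
    systems into osmosis and diffusion subsystems. Inverse routines estimate
    per-solute osmotic coefficients and the system-level osmosis coefficient
    from measured pressures or osmometer readings, with built-in validation
    suites against published sucrose osmometry and body-fluid osmolarity data.
    Includes a command-line interface for batch computation over CSV solute
    tables and JSON system specifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
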