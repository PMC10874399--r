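Package: ribocomp
Title: Growth-Optimal Ribosome Composition by Resource Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained resource balance analysis (RBA) of a
    self-fabricating cell, used to study how the RNA/protein composition of
    the ribosome affects the maximum growth rate. Provides the
    growth-rate-parameterized constraint system of the model (base and
    RNA-degradation-extended variants), a numeric optimizer (linear
    feasibility plus bisection on growth rate, with exhaustive vertex
    enumeration of the flux polytope), an analytic closed form for the base
    model via the determinant method, upper bounds on growth rate from the
    two autocatalytic loops (ribosomal protein and RNA polymerase/rRNA
    synthesis), and pipelines for composition sweeps, degradation-rate
    calibration, and archaeal/mitochondrial scenario variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
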