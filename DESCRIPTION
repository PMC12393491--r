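Package: capdyn
Title: Co-Activation Pattern Dynamics and Control Energies on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extraction of recurring co-activation brain states from regional
    BOLD time series by k-medoids clustering with correlation distance,
    quantification of their temporal dynamics (dwell time, fractional
    occupancy, transition/exit/enter probabilities), phase-randomized
    surrogate null models, and network-control-theoretic transition, exit and
    enter energies on weighted structural connectomes. Includes a synthetic
    cohort generator with planted states, Markov state sequences, AR(1)
    noise, modular connectomes and clinically coupled scores, so the whole
    pipeline can be exercised and validated end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
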