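Package: mrnpwalk
Title: Aging Levy Walk Analysis of Dendritic mRNP Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of bidirectional messenger
    ribonucleoprotein (mRNP) transport in neuronal dendrites recorded by
    single-particle tracking. Simulates the aging Levy walk with rests
    (ballistic runs alternating with heavy-tailed static rests), segments
    one-dimensional kymograph trajectories into run and rest phases with an
    iterative bilateral filter, fits power-law and truncated power-law
    sojourn-time distributions under finite observation-window and
    time-resolution corrections, computes time- and ensemble-averaged mean
    squared displacement, aged displacement distributions and ergodicity
    breaking (amplitude scatter) statistics, infers aging times from the
    stationary-trajectory fraction, selects two-population aging mixtures,
    and provides single-molecule FISH spot colocalization and linear density
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
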