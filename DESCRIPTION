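Package: centroidMSD
Title: Mean Square Displacement Theory and Simulation for a
    Focal-Adhesion Centroid Jump Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates a discrete-time jump process for amoeboid cell
    motion in which focal adhesions stochastically attach and detach and
    the cell centroid jumps to the (weighted) mean of the attached sites.
    Provides the closed-form theory for this process: the stationary
    distribution of the attachment count, the mean per-event displacement,
    an approximate mean square displacement (AMSD) at one event lag built
    from sequential-configuration displacement algebra, lower and upper
    bounds on the MSD, a worst-case displacement recurrence analysis, and
    a quadratic MSD-versus-lag approximation.  Also includes time-averaged
    and ensemble-averaged MSD estimators for event-indexed trajectories,
    lossless CSV trajectory persistence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
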