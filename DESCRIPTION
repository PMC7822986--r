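Package: cihealth
Title: Neural-Health Estimates for Cochlear Implant Users
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for three proposed estimates of
    spiral-ganglion neural health in cochlear implant users: multipulse
    integration (MPI, the drop in detection threshold from 80 to 1000
    pulses per second), the polarity effect (PE, the threshold difference
    between cathodic- and anodic-centred quadraphasic pulse trains) and
    the interphase-gap (IPG) offset between ECAP amplitude growth
    functions measured at short and long interphase gaps. Includes a
    population simulator of spiral ganglion neurons with separate
    peripheral and central exponential integrate-and-fire spike-initiation
    sites, degeneration and demyelination manipulations, an adaptive
    one-up/one-down staircase engine with virtual listeners, the
    within-subject (mean-centred, random-subject) correlation analysis
    with Fisher r-to-z confidence intervals, and a synthetic-study
    generator for end-to-end testing and parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
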