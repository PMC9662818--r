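Package: linchamber
Title: Single-Unit and Behavioral Analysis for Linear-Chamber Social-Interaction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tetrode single-unit recordings acquired while
    a mouse explores a 45 x 10 cm linear chamber with empty, social and object
    targets. Converts pose-estimation tracking tables into labeled behavioral
    intervals (sniffing, in-zone, center, proximal/distal interaction), applies
    waveform-based putative excitatory/inhibitory classification and unit
    quality filters, calls target-responsive neurons by auROC against a
    label-permutation null, decodes targets from trial firing rates with a
    linear support vector machine under leave-one-out cross-validation,
    summarizes sliding-window firing-rate dynamics (range, sigma, maximum
    delta firing rate), analyses interspike-interval bursting, extracts
    intrinsic excitability features from current-clamp sweeps, and ships a
    seeded synthetic-experiment generator so the whole pipeline runs without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
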