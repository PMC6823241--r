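Package: msadapt
Title: Monoamine-Stress Network Models of Neuroadaptation to Chronic
    Antidepressants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds, trains, and analyzes recurrent networks of sigmoidal
    units that represent the monoaminergic neurotransmitter systems
    (serotonin, norepinephrine, dopamine) and the hypothalamic-pituitary-
    adrenal stress axis.  Networks are trained to literature-derived
    steady-state targets with recurrent back-propagation, pruned by lesion
    sensitivity, and then analyzed for homeostatic neuroadaptation to
    chronically administered drugs and hormones: exhaustive enumeration of
    transmitter-system-component (TSC) strength configurations, screening
    of drug/hormone combinations against monoamine reference vectors,
    full-range individual-weight adjustment (FRIWA) sensitivity and
    correlation analysis, and bounded temporal-logic checking of leads-to
    propositions over adjustment trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
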