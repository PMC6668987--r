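Package: OptoFeed
Title: Closed-Loop Optogenetic Feeding Assays: Detection, Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capacitance-based closed-loop optogenetic feeding
    experiments in flies. Implements the real-time running-minimum trigger
    that gates an LED on food contact, a post hoc sip caller for recorded
    capacitance traces, a seeded agent-based simulator of two-choice fly
    feeding under optogenetic valence feedback, and the standard behavioral
    analytics (preference indices, cumulative timecourses, exclusion rules,
    dye-ingestion scoring, dose-response summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
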