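Package: curtailr
Title: Turbine Curtailment Prescriptions and AI Identification Accuracy for
    Avian Collision-Risk Systems
Version: 0.1.0
Authors@R: person("Manzana", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate automated bird-detection systems installed at
    wind-power projects. Implements a geometric curtailment prescription
    engine (confidence threshold, time-to-collision against rotor-swept
    zones, inner and outer decision cylinders, timed release hold), track
    ingestion with multi-target and image-availability filters and
    two-reviewer adjudication, confusion-matrix accuracy and error rates
    stratified by time period and camera tower, per-week curtailment-order
    summaries by target class and distance to the rotor-swept zone, turbine
    coverage classification from camera detection ranges, and a seeded
    synthetic-data generator (correlated-random-walk flight tracks plus a
    confusion-model classifier) so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
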