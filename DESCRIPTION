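Package: opsim
Title: Stochastic Simulation of Overdose Prevention Site Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time stochastic compartmental ("Markov-type") model of
    opioid use in an urban population with an optional overdose prevention
    site (OPS). Users move between not-using, using (outside or inside the
    OPS), treatment/recovery, nonfatal-overdose and fatal-overdose states on
    a 30-minute grid; attendance at the OPS decays with distance and is
    limited by finite capacity. The package includes closed-form rate
    conversions and analytic oracles, a distance-ring geography with
    exponential distance-decay visit probabilities, a calibrated synthetic
    overdose-record generator that reproduces published spatial and
    demographic summaries, a per-agent microsimulation oracle for the
    compartmental engine, and scenario drivers for capacity, in-site safety
    and treatment-rate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
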