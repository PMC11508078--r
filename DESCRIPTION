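Package: merisk
Title: Microenvironment Exposure and Health Risk Assessment for Particulate
    Matter and Trace Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-activity-weighted exposure modelling for air pollutants
    measured in household and roadside microenvironments, with the US-EPA
    style health-risk chain built on top: exposure duration, average daily
    dose, hazard quotient and hazard index for PM2.5 and PM10, and
    three-route (inhalation, ingestion, dermal) noncancer and lifetime
    cancer risk for trace elements bound to PM10. Ships the activity-profile
    and toxicology registries needed for a twelve-microenvironment adult
    receptor, a synthetic measurement generator (lognormal particulate
    series, zero-truncated normal element series, detection-limit censoring,
    laboratory QA simulation), and a deterministic reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
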