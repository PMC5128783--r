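Package: herdstress
Title: Stress-Response Analysis of Dairy Cattle Around Autonomous Robot
    Scrapers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a repeated-measures welfare study of dairy cows
    exposed to autonomous robot scrapers: interbeat-interval (RR) artifact
    detection and correction with five-type error classification, windowed
    RMSSD heart-rate-variability computation stratified by behavioural
    state and by robot proximity, ethogram time-budget analysis over a
    14-h observation schedule, fecal cortisol-metabolite summaries, and
    REML linear mixed-effects period contrasts with Satterthwaite degrees
    of freedom.  Includes a synthetic-herd generator that emulates the
    3-farm x 12-cow four-period study design so the full pipeline is
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
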