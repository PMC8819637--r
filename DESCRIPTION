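Package: prepcost
Title: Micro-Costing of Community-Based PrEP Delivery with Effective-Use Counselling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ingredients-based micro-costing pipeline for community-delivered
    HIV pre-exposure prophylaxis (PrEP) programmes serving adolescent girls and
    young women. Converts time-and-motion observation logs, salary schedules,
    expenditure ledgers and visit schedules into per-category annual costs and
    cost per person-month of PrEP under three costing scenarios (as implemented,
    Department of Health input prices, and at-scale Department of Health), with a
    staff-time bottleneck model of clinic capacity and seeded synthetic-data
    generators so the full pipeline runs without access to the underlying trial
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tibble,
    dplyr,
    tidyr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
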