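Package: beamletqa
Title: Beamlet Sequence Log Analysis for Binary-MLC Ring-Gantry Radiotherapy QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance toolkit for ring-gantry radiotherapy machines
    equipped with a binary multi-leaf collimator (MLC). Reads and writes an
    open CSV dialect (BLSQ) of beamlet sequence files, compares daily delivery
    logs against the treatment plan at each couch position to detect skipped
    firing positions and misfires, reconciles delivered monitor units against
    the plan, computes leaf-modulation metrics and aggregation heatmap
    matrices, and summarizes performance across fractions and patients with
    linear-fit and correlation analyses. A synthetic plan generator and
    delivery simulator with fault injection provides ground truth for every
    analysis stage in place of proprietary vendor logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
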