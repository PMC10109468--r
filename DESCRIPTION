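Package: palycensus
Title: Citizen-Science Consensus and Census for In Situ Microfossil Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running and evaluating a crowdsourced in-situ
    microfossil survey on tiled scanning electron microscope (SEM)
    montages. Models the montage acquisition geometry (tile footprint,
    overlap, unique imaged area, acquisition-time budget), aggregates
    volunteer questionnaire transcriptions with a quorum-based consensus
    decision tree including dispute flagging, builds and costs the
    expert-review queue, and computes an overlap-aware palynomorph census
    (unique-specimen counts, relative abundance, specimens per square
    centimetre, overlooked-specimen extrapolation). A synthetic specimen
    field and volunteer simulator with calibrated error models makes the
    whole pipeline testable end to end without any platform export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
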