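Package: batsonar
Title: Biomimetic Binaural Sonar Simulation, Mapping and Echo Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and processing pipeline for bat-like
    echolocation with a single emitter and two ears. Synthesizes binaural
    wide-band chirp echoes from 2D virtual scenes, then detects echoes by
    matched filtering, matches them across ears, localizes reflectors from
    echo delay and interaural time difference, builds an inflated occupancy
    grid, navigates with a reactive bug algorithm, classifies echoes as
    plant-like (diffuse) or not (specular glint) with a small neural-network
    ensemble, and quantifies localization and mapping accuracy against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
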