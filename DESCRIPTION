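Package: mocar
Title: Droplet-Array Microbial Cultivation Imaging and Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing droplet-array single-cell
    cultivation experiments of the microbe observation and cultivation
    array (MOCA) type, in which bacteria are grown in microliter droplets
    on a grid of hydrophilic spots and monitored by time-lapse bright-field
    microscopy. Provides Poisson occupancy statistics for cell loading and
    dilution design, a ground-truthed synthetic image-stack generator with
    per-colony logistic growth and optional sporulation rebound, droplet
    ROI location and transmission extraction from frame stacks, microcolony
    counting, threshold growth-time estimation from normalized transmission
    curves, per-concentration summaries, and an end-to-end reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    ggplot2,
    jsonlite,
    rlang,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
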