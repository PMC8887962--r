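Package: neuroprobe
Title: Data Model, Wiring and File Interchange for Extracellular Neural Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A layered data model for extracellular neural probes used in
    electrophysiology: contacts, shanks, probes and probe groups, with rigid
    geometric transformations, programmatic generators for standard silicon
    probe layouts, channel mapping ("wiring") of contacts to acquisition-device
    indices via composable per-stage permutation tables, readers and writers
    for the community JSON probe-description format and the legacy '.prb'
    dialect used by spike sorters, retrieval of vendor probe definitions from
    the public online probe library with local caching, and a testable
    geometry layer for plotting probes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    ggplot2,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'probe.R'
    'probegroup.R'
    'io-json.R'
    'library.R'
    'viz.R'
    'plot.R'
    'cli.R'
    'generators.R'
    'io-prb.R'
    'neuroprobe-package.R'
    'shank.R'
    'transforms.R'
    'wiring.R'
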