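Package: motorsync
Title: Analysis of Spontaneous Motor-Circuit Activity from Population Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous activity in developing motor
    circuits recorded by population calcium imaging. Implements automated
    cycle (transient) detection on fluorescence traces by derivative
    thresholding, grouping of cycles into episodes, classification of
    cycles as synchronous or asynchronous by a network participation rule,
    pairwise correlation and distance-correlation analyses, matching of
    optically detected cycles against intracellular voltage recordings,
    and baseline-normalised pharmacology comparisons. A ground-truthed
    simulator of developing-network activity (asynchronous and network
    events, distance-dependent recruitment, calcium-kernel rendering and
    paired voltage traces) makes every analysis stage verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
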