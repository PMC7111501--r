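Package: chmforge
Title: Scriptable Construction of Clustered Heat Maps with Replayable Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clustered heat maps from labeled numeric matrices the way an
    analyst would at the bench: parse a matrix from tab-delimited, CSV or xlsx
    input, clean and normalize it with a replayable transform/filter history,
    order rows and columns by agglomerative hierarchical clustering (or keep or
    randomize the original order), attach discrete and continuous covariate
    bars, control body colors through breakpoint color maps, and export the
    result as a deterministic zip archive around a properties document, as a
    multi-page PDF, and as a creation log from which the whole build can be
    replayed byte-identically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    grid,
    jsonlite,
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
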