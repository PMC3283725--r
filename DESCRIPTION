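Package: seqihc
Title: Sequential Chromogenic Immunohistochemistry Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed chromogenic immunohistochemistry performed by
    sequential staining, stripping and rescanning of a single tissue section.
    Provides a seeded simulator of multi-round brightfield slide scans with
    exported ground truth (Beer-Lambert stain rendering, sub-cellular puncta
    clutter, rigid inter-round misalignment, optional stripping carryover),
    blank-slide white balance and color inversion, rigid registration of rounds
    by phase correlation, the classic overlay schemes for co-localization and
    differential expression (multiplicative superimposition of an inverted
    round, two-color and multi-marker additive pseudocolor composites), cell
    detection with puncta rejection, per-cell co-expression classification and
    relative-expression quantification, and a stripping-completeness quality
    control metric. An end-to-end pipeline orchestrates the whole analysis as a
    reproducible, seeded run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
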