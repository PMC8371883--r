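Package: rrnallometry
Title: Allometric Scaling of Ribosomal Gene Content and Copy-Number
    Bias Correction for Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how cellular ribosomal (SSU rRNA) gene
    content, ploidy, DNA content and genome size scale with microbial
    cell volume, and for using the resulting allometric power law to
    correct taxon abundance profiles derived from rRNA gene surveys.
    Provides ln-ln least-squares power-law fitting with slope-comparison
    t tests, cell-volume geometry for simple shapes, conversion of
    per-taxon ribosomal gene frequencies into relative and absolute
    cell-number and biovolume community structure (optionally anchored
    to a qPCR total), a variable-width cell-size binning scheme, and
    synthetic trait-table and mock-community generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'bins.R'
    'traitTable.R'
    'correction.R'
    'simulate.R'
    'profileIO.R'
    'fit.R'
    'cli.R'
    'rrnallometry-package.R'
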