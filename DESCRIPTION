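Package: minibarcodes
Title: Design of Taxon-Specific DNA Mini-Barcodes from Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing taxon-specific DNA mini-barcodes from
    congeneric chloroplast genomes. Compares a pair of aligned plastomes to
    characterise their substitution spectrum, transition/transversion bias by
    annotation region, indels and hairpin-flanked microinversions; scans
    alignments with sliding-window nucleotide diversity to call divergence
    hotspots; evaluates candidate markers by Kimura 2-parameter
    nearest-neighbour species discrimination; and searches each marker for the
    shortest window that retains the full-length discrimination power. Includes
    seeded simulators of genome pairs and multi-species marker alignments with
    known planted truth, and a pipeline runner with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
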