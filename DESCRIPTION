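Package: polprof
Title: RNA Polymerase II Occupancy Profiling, Pausing Indices and Substrate Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchor-centred ChIP-seq occupancy analysis of RNA
    polymerase II and associated factors: binned, depth-normalised read
    densities around transcription start sites, transcription end sites or
    peak summits; fold enrichment of immunoprecipitated over input
    libraries; metagene aggregation over gene sets with bin-wise
    between-condition testing; promoter-proximal pausing indices under
    relaxed and stringent region definitions; hypergeometric gene-set
    overlap and core-promoter motif enrichment; and prioritisation of
    candidate phosphatase substrates from phosphopeptide intensity tables.
    Includes a compositional read simulator that plants recoverable
    recruitment, pausing, elongation and termination effects, providing a
    fully synthetic test bed with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    limma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
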