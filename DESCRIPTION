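Package: bifidotyper
Title: Species Identification of Bifidobacterium by hsp60 PCR-RFLP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico reconstruction of the hsp60 PCR-RFLP assay used to
    identify Bifidobacterium species: degenerate-primer amplicon prediction
    (H60F/H60R), restriction digestion with a small enzyme catalog, a gel
    model that turns fragment multisets into visible band sets (visibility
    window and co-migration merging), a packaged reference database of
    predicted HaeIII profiles for 30 type strains, discriminating-enzyme
    scoring, dichotomous-key construction, and identification of unknown
    isolates from observed gel band sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
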