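Package: hicdeconv
Title: Species-Level Deconvolution of Metagenome Assemblies from Hi-C Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bins draft metagenome assembly contigs into species-level groups
    using Hi-C proximity-ligation read pairs. Read pairs are filtered by
    distance to the nearest restriction site, tallied into a contig contact
    graph normalized by restriction-site counts, and clustered with a hybrid
    of Jarvis-Patrick shared-nearest-neighbor reweighting and average-linkage
    agglomeration. Includes enrichment-based estimation of the number of
    species, bootstrap stability assessment, length-weighted evaluation
    against reference truth tables, and a synthetic community plus Hi-C
    library simulator so the whole pipeline can be exercised offline.
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
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
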