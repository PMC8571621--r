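Package: landfuse
Title: Entropy-Weighted Fusion of Hierarchical Landscape Pattern Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuses the two grades of a hierarchical land-use/land-cover
    classification into single landscape pattern indicators. Class-level
    components of classic metrics (Shannon diversity, patch richness,
    number of patches) computed on the coarse grade are up-weighted by
    conditional-entropy weights that quantify the realized subclass
    heterogeneity of each coarse class, yielding fused indicators (FLIs)
    that retain the coarse-grade trend while recovering fine-grade
    detail. Includes circular moving-window surface computation, a
    Huffman-coding information-volume measure for comparing metric
    surfaces, surface-comparison statistics, a synthetic two-grade
    landscape generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
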