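Package: nsafq
Title: Label-Free Shotgun Proteomics Quantification with Normalized
    Spectral Abundance Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies label-free shotgun proteomics experiments from
    protein-level spectral counts using normalized spectral abundance
    factors (NSAF). Provides pseudo-count handling and log transformation,
    a replicate reproducibility filter, per-protein two-sample t-tests on
    log NSAF with Benjamini-Hochberg correction, sample-level diagnostics
    (Spearman correlation, hierarchical clustering, condition-vs-condition
    scatter tables), local Fisher-exact term enrichment with per-category
    summed NSAF abundance, and proteome-transcriptome fold-change
    concordance classification. A synthetic spectral-count generator with
    planted differential abundance and full ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
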