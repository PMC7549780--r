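Package: hybridase
Title: Allele-Specific Expression Misregulation Analysis for Interspecific
    Hybrid Embryo Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying stage-dependent gene expression in
    interspecific hybrids and their parental species from bulk mRNA
    sequencing. Provides a synthetic-data generator for diverged parental
    transcriptomes with planted regulatory programs, competitive
    dual-genome read classification with mismatch filtering for
    allele-specific counting, negative-binomial Wald tests of
    stage contrasts with explicit up/down/unaltered direction calls,
    cross-series concordance and regulatory-pattern classification that
    identifies hybrid-misregulated ("pattern D") genes, and one-sided
    Fisher gene-set overrepresentation, together with a seeded
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
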