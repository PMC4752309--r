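Package: spongemir
Title: Small-RNA miRNA Discovery and Conservation Analysis for Demosponges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering bona fide microRNAs
    from small RNA sequencing libraries of demosponges and comparing their
    conservation across species. Implements the full read-cleaning cascade
    (quality/adapter/length trimming, read collapsing, minimum-count and
    non-coding-RNA decoy filters), a seed-and-verify short-read mapper,
    read-stack based precursor excision with base-pair-maximisation hairpin
    folding, Dicer processing-signature metrics (3' overhang length, 5'-end
    homogeneity) and an additive candidate score, plus mismatch-tolerant
    matching against known miRNA sets, cross-species single-linkage
    clustering, arm-dominance calls, per-column conservation profiles and
    exact-match read tallies. A first-class synthetic-data module generates
    genomes with planted pre-miRNA hairpins and realistic read libraries with
    ground truth for recovery testing. All user-facing functions take and
    return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
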