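Package: hapld
Title: Short-Range Linkage Disequilibrium in Phased Haplotype Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of short-range linkage disequilibrium (LD) in phased,
    gap-aligned haplotype alignments such as cloned gene sequences from
    Anopheles gambiae s.l. populations. Computes per-gene polymorphism
    summaries (segregating sites, haplotype counts, nucleotide diversity
    including Nei-Gojobori synonymous and non-synonymous partitions),
    all pairwise two-locus LD statistics (D, D', r, r-squared) with exact-test
    significance and Bonferroni correction, LD-decay curves fitted to the
    Hill-Weir drift-recombination expectation by non-linear least squares and
    to a penalized cubic-spline smoother, haploblock grids, and segment-based
    Wilcoxon comparisons of mean r-squared across genes and species. Includes
    a coalescent-with-recombination haplotype simulator so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    mgcv,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
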