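Package: vqtlscan
Title: Mean and Variance-Heterogeneity Genome Scans for Expression QTL
    in Haploid Segregant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint mean-effect (Wilcoxon rank-sum) and variance-heterogeneity
    (Brown-Forsythe) genome scans of expression phenotypes in two-parent
    haploid segregant panels, with permutation-based false discovery rate
    estimation, greedy association-peak calling with cis/trans
    classification, regulatory-hotspot enrichment tests, genotype-phenotype
    map construction with interaction contrasts, and conditional scans
    within an anchor genotype for epistasis screening.  Includes a
    seedable synthetic-study generator (Markov-chain recombination under
    the Haldane map function, additive/epistatic/variance-effect
    architectures) so every stage is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
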