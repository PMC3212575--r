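Package: polyfst
Title: Detecting Polygenic Selection from Allele-Frequency Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study population differentiation at loci underlying a
    polygenic trait under stabilizing selection. Provides a forward-in-time
    Wright-Fisher simulator of diploid populations with recombination and
    Gaussian viability selection on an additive trait, per-SNP Weir-Cockerham
    (1984) unbiased F_ST estimation from genotype counts, and a candidate-set
    versus genomic-background comparison battery: SNP filtering, one-tailed
    Mann-Whitney tests, outlier trimming by background F_ST quantiles, removal
    of candidates in linkage disequilibrium with variants for other traits,
    and top-tail enrichment of haplotype-based selection scores. A
    Balding-Nichols panel generator produces HapMap-like genotype-count panels
    with known differentiation for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
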