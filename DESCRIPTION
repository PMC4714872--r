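Package: redmodules
Title: Mapping and Dating of Red Wing-Pattern Regulatory Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to localise adjacent cis-regulatory modules controlling
    discrete colour-pattern elements from multi-sample genotype and haplotype
    data, and to reconstruct their movement between species.  Implements a
    genotype-by-phenotype chi-squared association scan with Bonferroni
    control, sliding-window scans of fixed nucleotide differences with
    minimal-region delineation, diagnostic-site haplotype classification with
    recombination-breakpoint calling, neighbor-joining trees on pairwise
    p-distances with outgroup-rooted clade assignment, and a calibrated
    strict-clock estimator of allele divergence dates with site-bootstrap
    intervals.  A structured-coalescent simulator generates phased haplotype
    alignments, diploid genotype calls and phenotype tables under an explicit
    module-shuffling scenario (deep species split, interval-restricted
    introgression, within-species recombinants) with full ground truth, so
    every stage of the inference chain can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
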