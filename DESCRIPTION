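Package: founderpanel
Title: Founder-Population Reference Panels, Genotype Imputation and
    Population-Genetic Characterization
Version: 0.1.0
Authors@R:
    person("AGRP", "Toolkit Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates bottlenecked founder populations expanded through a
    known multi-generation pedigree (forward Wright-Fisher ancestral model,
    gene dropping with recombination, genotype-level noise injection), applies
    a sequencing-study quality-control cascade (genotype filters, Mendelian
    masking, exact Hardy-Weinberg test, site filters, concordance and
    sensitivity checks), selects pedigree-unrelated individuals, phases by
    transmission, assembles and merges phased haplotype reference panels, and
    imputes masked genotypes with a haploid Li-Stephens haplotype-copying HMM.
    Evaluation utilities reproduce the standard characterizations of founder
    cohorts: aggregate r-squared imputation accuracy by minor-allele-frequency
    bin across reference-panel configurations, best linear unbiased (BLUE)
    allele-frequency estimation on pedigrees, rare-variant depletion by
    resampling, drift enrichment, IBD/HBD segment sharing, and
    frequency-stratified deleteriousness comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
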