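Package: vctwas
Title: Variance-Component Transcriptome-Wide Association Testing
Version: 0.1.0
Authors@R:
    person("vctwas", "maintainers", email = "vctwas@example.org", role = c("aut", "cre"))
Description: Gene-based association testing that integrates reference
    cis-eQTL effect sizes with GWAS data. Implements a variance-component
    (SKAT-style) score test in which SNP effects on the phenotype are
    random with variance proportional to squared reference eQTL weights,
    for both individual-level and summary-level GWAS data, together with
    the weighted-burden (GReX imputation) comparator, elastic-net and
    dense shrinkage weight training, weight filtering, Fisher meta-analysis
    with FDR control, and a simulation harness for power and type-I-error
    studies under LD-structured synthetic genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
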