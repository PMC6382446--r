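Package: ntdburden
Title: Rare-Variant Filtering, Segregation and Poisson Burden Testing for
    Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for rare-variant discovery in case-control
    exome studies of neural tube defects and similar congenital disorders:
    a quality-control and annotation filter cascade over multi-sample VCFs
    (consequence class, population frequency, genotype quality, strand-split
    alternate-read support, allele balance, PolyPhen-2 impact), candidate-gene
    prioritization with family segregation and compound-heterozygote
    scanning from PED pedigrees, a per-gene exact Poisson rate-comparison
    burden test with allele-count exposures and Bonferroni correction, a
    replication-cohort mode, and a synthetic-cohort simulator for
    calibrating the test's type-I error and power at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
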