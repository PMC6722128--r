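Package: famseg
Title: Family-Based Rare-Variant Filtering, Association and Segregation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for family-based rare-variant analysis in affected-sibling
    designs: pedigree input/validation with an extended phenotype vocabulary,
    multi-sample VCF genotype handling with biallelic decomposition,
    centered-IBS kinship and X-heterozygosity sex checks, affected-only
    cross-family candidate variant filtering, allele-count association against
    reference populations (Yates-corrected chi-square with a fixed-margins
    Monte-Carlo and exact hypergeometric null), and a Mendelian segregation
    test under complete penetrance with exact pedigree peeling and
    gene-dropping simulation. Includes a synthetic cohort generator emulating
    an affected-sib-pair study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
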