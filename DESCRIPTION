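Package: trioburden
Title: Trio Exome Inheritance Classification and Case-Control Gene-Panel
    Burden Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for case-control studies of parent-offspring
    sequencing trios. Reads multi-sample VCF, pedigree (PED) and variant
    annotation tables; applies variant-level quality and annotation filters
    (population frequency, CADD, genotype quality, functional consequence);
    classifies each proband variant as de novo, transmitted or non-transmitted
    using read-depth, allelic-balance and parental-genotype evidence;
    restricts to user-supplied gene panels and computes case-control burden
    statistics including cross-product odds ratios with exact conditional
    (noncentral hypergeometric) confidence intervals, Pearson chi-square and
    Fisher exact tests; categorizes de novo variant genes by KEGG orthology;
    and simulates complete synthetic trio cohorts with a planted-variant truth
    table so that every pipeline stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
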