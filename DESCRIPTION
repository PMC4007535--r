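Package: asecis
Title: Allele-Specific Expression Analysis of Cis- and Trans-Regulatory
    Variation in X-Substitution Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting cis-, trans- and cis-by-trans regulatory
    variation from allele-specific microarray signals in chromosome
    substitution designs, with genomic DNA hybridizations as probe-affinity
    and allele-dosage controls. Provides a synthetic-data generator that
    emulates SNP probe sets (PM1/PM2/MM probes), probe affinities,
    cross-hybridization and DNA controls; probe-set summarization and
    per-slide median normalization; sequence- and discriminant-based
    assignment of probes to parental alleles; a per-gene heteroscedastic
    cell-means model with six DNA-controlled contrast families tested by
    Satterthwaite F-tests and grouped Benjamini-Hochberg FDR; overall
    expression contrasts (substitution, dominance, sex) with sex-bias
    classification; and the chi-square, Fisher, McNemar and Breslow-Day
    contingency analyses relating regulatory variation to sex bias and
    chromosomal location.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
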