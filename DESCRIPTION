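Package: gsrefresh
Title: Reference Population Updating Strategies for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulation of a closed livestock breeding
    population under genomic selection, with tools to study how the
    composition of the reference population shapes genetic merit, genetic
    diversity and prediction bias.  Implements genomic relationship
    matrices (VanRaden and allele-sharing similarity), marker quality
    control, weighted GBLUP with fixed variance components, optimal
    contribution selection under an expected rate-of-inbreeding cap with a
    minimum-coancestry fallback, pedigree inbreeding (tabular and
    Meuwissen-Luo algorithms), observed heterozygosity, standardized
    prediction bias, effective population size, and per-strategy
    generation trend estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
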