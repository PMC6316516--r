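Package: methcross
Title: Allele-Specific DNA Methylation Inheritance from Bisulfite Amplicon
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of allele-specific DNA methylation inheritance at short
    nuclear insertions of organellar DNA (NUMTs) across a Col x Ler cross of
    Arabidopsis thaliana. Provides a seeded bisulfite amplicon read simulator
    for the full cross design (parents, reciprocal F1, selfed F2) with known
    ground truth, bisulfite-space allele assignment of reads by diagnostic
    SNPs, per-site methylation calling in CpG/CpHpG/CpHpH contexts, weighted
    and fractional methylation estimators, Mendelian segregation tests,
    reciprocal-cross distribution comparisons, population summaries, and
    trans-allelic Spearman correlation with regression in F2 heterozygotes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
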