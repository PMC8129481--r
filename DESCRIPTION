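Package: lipoproteomr
Title: Comparative Lipoprotein Proteomics and Mendelian Randomization Pipeline
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the protein cargo of lipoprotein(a) and
    low-density lipoprotein particles and to screen the plasma proteome for
    effects of lifelong lipid exposure. Implements label-free differential
    enrichment (median normalization, low-percentile noise imputation,
    quantifiability filtering, paired and empirical-Bayes moderated t-tests,
    Benjamini-Hochberg control, discovery/replication logic), targeted
    parallel-reaction-monitoring absolute quantification against heavy-peptide
    standards, and a two-sample Mendelian-randomization screen (instrument
    selection, LD clumping, allele harmonization, Wald ratios,
    inverse-variance-weighted meta-analysis, Bonferroni screening). Seeded
    synthetic-data generators reproduce the statistical structure each stage
    assumes so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
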