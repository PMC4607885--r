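Package: cncnet
Title: Coding-Non-Coding Co-Expression Networks and Cadmium Toxicity
    Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-group lncRNA/mRNA microarray analysis: quantile
    normalization, fold-change plus t-test differential-expression screening,
    GO enrichment with elim pruning on the ontology DAG, pathway enrichment
    with Benjamini-Hochberg false discovery rate control, and construction of
    bipartite coding-non-coding co-expression networks by Pearson-correlation
    thresholding with k-core decomposition and single-lncRNA subnetwork
    extraction. Companion statistics for exposure-biomarker cohorts (Pearson,
    Spearman and partial correlation, one-way ANOVA with Dunnett contrasts,
    chi-square tests on damage rates, 2^-ddCt relative quantification) and
    comet-assay DNA-damage metrics (tail length, tail DNA fraction, tail
    moment, Olive tail moment) are included, together with a synthetic-data
    generator that plants known differential expression, co-expression
    modules, enriched ontology terms, cohort correlation structure and comet
    tail fractions so every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    fgsea,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    jsonlite
Config/testthat/edition: 3
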