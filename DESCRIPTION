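Package: aphidfit
Title: Host-Plant Fitness Analytics for Aphids: Life Tables, Feeding
    Behavior, and Salivary-Gland Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how well a parthenogenetic aphid clone
    performs on alternative host plants, integrating three lines of
    evidence. (1) Age-stage cohort demography: survival and fecundity
    schedules from daily individual life histories, the Euler-Lotka
    intrinsic rate of increase solved by bisection, net reproductive rate,
    finite rate of increase and mean generation time, all with bootstrap
    standard errors. (2) Electrical penetration graph (EPG) feeding
    behavior: per-waveform time ratios over fixed-length recordings, group
    comparison by Welch t-test or one-way ANOVA with Tukey letters, and
    feeding-step attainment matrices. (3) Replicate-free differential
    expression between pooled RNA-seq libraries: RPKM, trimmed mean of
    M-values (TMM) normalization, the Audic-Claverie exact Poisson test,
    Benjamini-Hochberg adjustment, fold-change/alpha calling and Venn set
    partitioning, followed by GO-term enrichment (chi-square with Fisher
    fallback) with is_a annotation propagation and ontology-level
    filtering. A synthetic-data module generates cohorts, EPG recordings,
    count matrices and GO annotations with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'de.R'
    'enrich.R'
    'epg.R'
    'io.R'
    'lifetable.R'
    'synthdata.R'
    'utils.R'
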