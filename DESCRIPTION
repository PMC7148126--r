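Package: rifachase
Title: mRNA Decay Kinetics, Transcript Production Rates, and Leader
    Classification from Rifampin-Chase qPCR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating bacterial mRNA half-lives from
    rifampin-chase qPCR threshold-cycle time courses, including biphasic
    decay segmentation that restricts fitting to the initial fast phase;
    inference of steady-state transcript production rates from abundance,
    degradation and growth-dilution constants; translation-efficiency and
    percent-of-reference construct summaries; 5' UTR length computation,
    leaderless/leadered classification and Shine-Dalgarno scanning from
    TSS/start-codon annotations; the statistical comparison battery used
    for such designs (Spearman correlation, slope-equality ANCOVA,
    Mann-Whitney, Kruskal-Wallis/Dunn, ANOVA/Tukey); an explicit two-pool
    kinetic simulator quantifying how partitioning between a translated
    and a rapidly degraded "dark matter" pool biases inferred production
    rates; and a synthetic-data generator producing every input table the
    pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
biocViews: Transcriptomics, GeneExpression, qPCR, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
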