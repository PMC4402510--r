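Package: modlm
Title: Gene-Wise Linear Models with Empirical Bayes Moderation for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential expression analysis for microarray log-intensities
    and RNA-seq counts built around gene-wise linear models whose residual
    variances are moderated by an empirical Bayes squeeze towards a common or
    trended prior. Includes normal-exponential background correction, quantile
    and cyclic loess normalization, TMM scale factors, the voom mean-variance
    precision-weight transformation for counts, consensus intrablock
    correlation, sample quality weights, moderated t/F/B statistics, TREAT,
    rank-based and rotation gene set tests (roast, romer), a correlation-
    adjusted competitive test (camera), hypergeometric enrichment, differential
    exon usage, multidimensional scaling on leading fold changes, and
    synthetic-data generators with ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    optparse,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
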