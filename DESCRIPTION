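Package: binmeta
Title: Binary-Effects Meta-Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting heterogeneity in meta-analyses of
    genome-wide association studies under the binary effects assumption:
    each study either carries the effect or it does not, and where present
    the effect sizes are similar. Implements the m-value, the posterior
    probability that an effect exists in each study, computed jointly
    across studies by exact enumeration of effect configurations or by
    Metropolis-Hastings sampling; the P-M plot for visualising per-study
    p-values against m-values; fixed-effects weighted-z, Han-Eskin
    random-effects and Wakefield asymptotic Bayes factor tests; and the
    binary effects association test whose p-value is estimated by
    importance sampling. A case-control summary-statistic simulator and
    experiment harnesses (false-positive rate, m-value histograms, ROC
    comparison, power) support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
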