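Package: rtadte
Title: Differential Transcript Expression on Uncertainty-Scaled Counts
Version: 0.1.0
Authors@R:
    person("rtadte", "developers", email = "rtadte@example.org", role = c("aut", "cre"))
Description: Estimates the technical overdispersion that read-to-transcript
    ambiguity (RTA) induces in transcript-level RNA-seq quantifications,
    using the bootstrap resamples produced by Salmon or kallisto, and divides
    it out of the counts so that scaled counts follow the classical negative
    binomial mean-variance relationship. Includes readers and writers for the
    Salmon and kallisto output dialects, a quasi-Poisson moment estimator of
    the RTA overdispersion with empirical Bayes moderation, expression
    filtering and TMM normalization, a negative binomial generalized linear
    model engine with trended dispersion and quasi-likelihood F-tests, a
    count-level simulator with equivalence-class bootstrap resampling and
    brute-force ground-truth overdispersion, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma
Config/testthat/edition: 3
NeedsCompilation: yes
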