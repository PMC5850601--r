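Package: seltraj
Title: Selection Parameter Inference from Replicated Allele-Frequency Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation of selection coefficients (s) and dominance (h) from
    replicated Pool-Seq allele-frequency time series, as produced by Evolve and
    Resequence (E&R) experiments. Provides a Wright-Fisher forward simulator for
    unlinked loci with Pool-Seq sampling noise, linear least squares estimation
    on logit-transformed trajectories with a discrete-generation bias
    correction, nonlinear least squares co-estimation of s and h, a parametric
    bootstrap test against the null hypothesis of neutral drift, classic
    chi-squared and Cochran-Mantel-Haenszel tests, sync-format input/output,
    and an evaluation suite (relative RMSE maps, power curves, design sweeps)
    for planning E&R experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
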