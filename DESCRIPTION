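Package: sweepstakes
Title: Multiple-Merger Coalescent Model Comparison for Site-Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing sweepstakes reproduction hypotheses in highly
    fecund populations from genome-wide site-frequency spectra (SFS). Implements
    exact expected branch-length spectra and Monte Carlo genealogy simulators for
    the Kingman coalescent with exponential growth, the haploid Lambda-Beta and
    diploid Xi-Beta(2-alpha, alpha) coalescents of random sweepstakes, and the
    Durrett-Schweinsberg coalescent of recurrent selective sweeps, plus a
    restricted two-locus extension of the latter for linkage-disequilibrium
    decay. Models are fitted to an observed SFS by adaptive approximate Bayesian
    computation MCMC or grid search on logit-normalized SFS summaries, with
    log-odds residual diagnostics, bootstrap error bands, SFS-based neutrality
    test statistics (Tajima's D, Fu and Li's D, Fay and Wu's H, Zeng's E),
    sliding-window scans, and McDonald-Kreitman selection measures. Synthetic
    data generators emulate fragment-ensemble spectra, SNP misorientation, and
    per-gene McDonald-Kreitman tables so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
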