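Package: asvherit
Title: Average Semivariance Estimation of Marker-Associated Genetic
    Variance and Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased estimation of the fraction of genetic variance (p)
    and marker heritability (H2_M) explained by large-effect marker loci
    in replicated and unreplicated populations. Conventional ANOVA/REML
    variance-component ratios are upwardly biased by a design-dependent
    coefficient k_M; this package computes k_M for balanced and
    unbalanced genotypic data (closed forms and the centering-trace
    formula), converts conventional (average marginal variance) fits to
    the average semivariance scale on which p and H2_M are unbiased, and
    provides ANOVA method-of-moments and REML estimators, delta-method
    and bootstrap standard errors, Type I/II/III fixed-effects sums of
    squares for multilocus models, and a simulation engine for the
    standard study designs used to characterise the bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
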