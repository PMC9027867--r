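Package: cacyreus
Title: Abundance and Habitat-Suitability Modelling for the Geranium Bronze
    Butterfly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the distribution of the geranium bronze
    (Cacyreus marshalli), an alien butterfly strictly dependent on
    ornamental Pelargonium, in Alpine landscapes. Provides a synthetic
    landscape and survey-design generator (250 m grid, elevation lapse
    temperatures, urban host-plant census, stratified altitudinal
    sampling); binomial N-mixture models for repeated egg counts with
    Poisson, negative binomial and zero-inflated Poisson abundance
    mixtures, AICc-based two-step covariate selection, parametric
    bootstrap goodness-of-fit and overdispersion (c-hat) inflation; a
    presence-only maximum-entropy suitability model with buffered
    background sampling, variable contributions and TSS evaluation; and a
    scenario engine projecting expected egg abundance under climate
    warming and host-plant reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
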