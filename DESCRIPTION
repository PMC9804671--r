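Package: ordqual
Title: Statistical-Preference Comparison of Healthcare Provider Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares the quality of healthcare providers from ordinal or
    cardinal quality data on a common basis using the statistical preference
    criterion. Provides pairwise quality differences (probability that a
    random patient of one provider fares strictly better than one of
    another), provider-level comparative quality indices, and "lottery"
    indices of quality variation within and between provider groups, with a
    between-group Gini identity for cardinal scores. Includes indirect
    standardization of provider quality profiles for socio-demographic
    composition via per-cutoff distribution regression (linear-probability
    or probit-binomial), clustered bootstrap standard errors that resample
    providers within groups, and a synthetic-data generator emulating
    multi-provider ordinal survey data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
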