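Package: gsimpson
Title: Generalized Simpson's Entropy for Biodiversity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures species diversity with the generalized Simpson's
    entropy zeta_r = sum_s p_s (1 - p_s)^r, the probability that the
    (r+1)st individual sampled from a community belongs to a previously
    unseen species. Provides the exact index for known communities, its
    uniformly minimum variance unbiased estimator from abundance data,
    delta-method standard errors and asymptotic confidence intervals,
    entropy and effective-number (diversity) profiles with pointwise
    envelopes, two-community difference profiles with a significance
    summary, jackknife species-richness estimation (orders 1-5 with
    sequential order selection) to bound the valid profile order,
    comparator indices (HCDT/Tsallis entropy, Hill numbers, Hurlbert's
    index with its unbiased rarefaction estimator and effective number),
    and a synthetic-community toolkit with an exact multinomial
    enumeration oracle for unbiasedness and coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
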