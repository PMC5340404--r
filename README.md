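# gsimpson

Species diversity estimation with **generalized Simpson's entropy**

```
zeta_r = sum_s p_s (1 - p_s)^r,    r = 1, 2, ...
```

the probability that the (r+1)st individual sampled from a community
belongs to a species not seen among the first r — the slope of the species
accumulation curve at rank r+1. `1 - zeta_1` is the classical Simpson
index; larger orders `r` weight rare species more heavily, and the index is
a valid diversity measure (maximal at the uniform community) for
`r <= S - 1`.

The family's practical advantage for ecologists working with
under-sampled, species-rich communities (tropical forest inventories,
microbial surveys) is that it admits an **exactly unbiased estimator** at
every order below the sample size,

```
Z_r = sum_s p'_s * prod_{j=1..r} (1 - (n'_s - 1)/(n - j)),
```

together with delta-method standard errors and asymptotic confidence
intervals — unlike Hill/HCDT diversities, whose plug-in estimators are
badly biased exactly where the data are thin. The package provides:

- the true index, information function, and effective number of species
  `1 / (1 - zeta_r^(1/r))` for known communities;
- the unbiased estimator `Z_r`, standard errors, confidence intervals, and
  entropy/diversity profiles with pointwise envelopes;
- two-community difference profiles with a significance summary
  ("is zero ever inside the envelope?");
- Burnham–Overton jackknife richness (orders 1–5, sequential order
  selection) to bound the valid profile order `r <= S_hat - 1`;
- comparator indices: HCDT (Tsallis) entropy, Hill numbers (plug-in),
  Hurlbert's index with its unbiased rarefaction estimator and effective
  number, and seeded bootstrap envelopes;
- a synthetic-community toolkit (uniform / geometric / log-series / Zipf,
  seeded multinomial sampling) and an exact multinomial enumeration oracle
  used to verify unbiasedness *exactly*;
- a command-line tool (`exec/gsimpson`) with subcommands `profile`,
  `compare`, `richness`, `simulate`, `hurlbert`, `hill`.

Everything is tibble-first: samples and profiles are data frames, results
have `tidy()`/`glance()` methods, and profiles have `autoplot()` methods.

## Worked example

Two synthetic forest plots: plot 6 sampled from a geometric community
(S = 60, ratio 0.90), plot 18 from a richer, more even geometric community
(S = 120, ratio 0.95); 600 stems each.

```r
library(gsimpson)

plot6  <- sample_community(make_community("geometric",  60, 0.90), n = 600, seed = 101)
plot18 <- sample_community(make_community("geometric", 120, 0.95), n = 600, seed = 102)

jackknife_richness(plot6)
#> Jackknife richness estimate (order 1): 55.98 species
#>   observed: K = 46 species in n = 600 individuals; f = (10, 6)

zeta_profile(plot6, max_order = 5, scale = "diversity")
#> <zeta profile: diversity scale, orders 1..5, n = 600, K = 46, 95% pointwise envelope>
#> # A tibble: 5 x 7
#>   order estimate  sigma lower upper scale     level
#>   <int>    <dbl>  <dbl> <dbl> <dbl> <chr>     <dbl>
#> 1     1     17.6 0.0720  16.0  19.6 diversity  0.95
#> 2     2     17.8 0.131   16.2  19.8 diversity  0.95
#> 3     3     18.0 0.179   16.4  20.0 diversity  0.95
#> 4     4     18.3 0.218   16.7  20.1 diversity  0.95
#> 5     5     18.5 0.249   16.9  20.3 diversity  0.95
```

Read: at order 1 the plot behaves like ~17.6 equally common species, with a
95% interval of (16.0, 19.6); the gentle rise with `r` reflects the rare
tail. Comparing the plots:

```r
d <- zeta_difference_profile(plot18, plot6, max_order = 10)
significance_summary(d)
#> significant at every order: zero is outside the 95% pointwise envelope
#> at all 10 orders; identical diversity is rejected.

match_q(plot6, r = 1)  # HCDT order with the same effective number as r = 1
#> [1] 2
```

From a shell, the same analysis:

```sh
gsimpson simulate --family geometric --S 60 --param 0.90 --n 600 --seed 101 --out plot6.tsv
gsimpson profile plot6.tsv --max-order 5 --scale diversity
gsimpson compare plot18.tsv plot6.tsv --max-order 10
```

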