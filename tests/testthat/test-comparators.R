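test_that("HCDT entropy hits its special cases", {
  expect_equal(hcdt_entropy(c(0.5, 0.5), 2), 0.5)           # = zeta_1
  expect_equal(hcdt_entropy(c(0.5, 0.3, 0.2), 0), 2)        # S - 1
  expect_equal(hcdt_entropy(c(0.5, 0.5), 1), log(2))        # Shannon limit
  # continuity at q = 1
  expect_equal(hcdt_entropy(c(0.6, 0.4), 1 - 1e-10),
               hcdt_entropy(c(0.6, 0.4), 1), tolerance = 1e-6)
  expect_error(hcdt_entropy(c(0.5, 0.5), -0.5), class = "gsimpson_domain_error")
  # the link to generalized Simpson's entropy: 2T = zeta_1
  set.seed(4)
  comm <- random_community(8)
  expect_equal(hcdt_entropy(comm, 2), zeta(comm, 1))
})

test_that("Hill diversity is the HCDT effective number", {
  expect_equal(hill_diversity(rep(0.2, 5), c(0, 0.5, 1, 2)), rep(5, 4))
  expect_equal(hill_diversity(c(0.5, 0.5), 2), 2)
  expect_equal(hill_diversity(c(0.6, 0.4), 2), 1 / 0.52)
  expect_equal(hill_diversity(c(0.6, 0.4), 1),
               exp(-0.6 * log(0.6) - 0.4 * log(0.4)))
  # decreasing in q for non-uniform communities
  qs <- seq(0, 4, by = 0.25)
  d <- hill_diversity(c(0.7, 0.2, 0.1), qs)
  expect_true(all(diff(d) < 0))
})

test_that("match_q solves Hill diversity = generalized Simpson diversity", {
  # r = 1 must give exactly q = 2 for any non-uniform community
  set.seed(8)
  for (i in 1:10) {
    comm <- random_community(sample(2:12, 1)) # almost surely non-uniform
    expect_equal(match_q(comm, 1), 2, tolerance = 1e-8)
  }
  # general order: verified against a brute-force grid search
  comm <- community(c(0.6, 0.4))
  q2 <- match_q(comm, 2)
  grid <- seq(0, 4, by = 1e-4)
  target <- effective_number(zeta(comm, 2), 2)
  qgrid <- grid[which.min(abs(hill_diversity(comm, grid) - target))]
  expect_equal(q2, qgrid, tolerance = 2e-4)
  expect_equal(hill_diversity(comm, q2), target, tolerance = 1e-8)

  expect_error(match_q(rep(0.25, 4), 2), class = "gsimpson_degenerate_error")
})

test_that("Hurlbert's index matches its closed identities", {
  set.seed(15)
  comm <- random_community(6)
  expect_equal(hurlbert_index(comm, 1), 1)
  expect_equal(hurlbert_index(comm, 2), 1 + zeta(comm, 1))
  expect_equal(hurlbert_index(rep(0.25, 4), 2), 1.75)
  # increasing in k, bounded by S, approaching S
  ks <- c(1, 2, 5, 10, 50, 500)
  h <- hurlbert_index(comm, ks)
  expect_true(all(diff(h) > 0))
  expect_true(all(h <= 6))
  expect_equal(h[length(h)], 6, tolerance = 1e-3)
  expect_error(hurlbert_index(comm, 0), class = "gsimpson_invalid_order")
})

test_that("the rarefaction estimator of Hurlbert's index is exactly unbiased", {
  for (comm in list(community(c(2 / 3, 1 / 3)), community(c(0.5, 0.3, 0.2)))) {
    p <- comm$prob
    for (n in 2:5) {
      for (k in seq_len(n - 1)) {
        eh <- enumerate_expectation(comm, n, function(s) hurlbert_estimate(s, k))
        expect_equal(eh, hurlbert_index(comm, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("Hurlbert estimator edge identities hold on every sample", {
  set.seed(19)
  for (i in 1:15) {
    smp <- sample_community(random_community(sample(2:10, 1)),
                            n = sample(5:50, 1))
    n <- sum(smp$count)
    expect_equal(hurlbert_estimate(smp, 1), 1, tolerance = 1e-12)
    expect_equal(hurlbert_estimate(smp, n), nrow(smp), tolerance = 1e-9)
    # cross-module identity with the unbiased Simpson estimator
    expect_equal(hurlbert_estimate(smp, 2), 1 + zeta_estimate(smp, 1),
                 tolerance = 1e-12)
  }
  expect_equal(hurlbert_estimate(c(2, 1), 2), 5 / 3)
  expect_error(hurlbert_estimate(c(2, 1), 4), class = "gsimpson_invalid_order")
})

test_that("Hurlbert effective numbers invert the index", {
  expect_equal(hurlbert_effective_number(1, 5), 1)
  expect_equal(hurlbert_effective_number(2 - 1 / 5, 2), 5, tolerance = 1e-6)
  # forward-then-invert round trip on a uniform community
  h <- hurlbert_index(rep(1 / 7, 7), 10)
  expect_equal(hurlbert_effective_number(h, 10), 7, tolerance = 1e-6)
  expect_identical(hurlbert_effective_number(2, 2), Inf)
  expect_error(hurlbert_effective_number(0.5, 3), class = "gsimpson_domain_error")
  expect_error(hurlbert_effective_number(4, 3), class = "gsimpson_domain_error")
})

test_that("bootstrap envelopes are reproducible and cover the truth", {
  smp <- sample_community(make_community("uniform", 10), 500, seed = 77)
  stat <- function(s) hurlbert_estimate(s, 20)
  b1 <- bootstrap_envelope(smp, stat, B = 300, seed = 99)
  b2 <- bootstrap_envelope(smp, stat, B = 300, seed = 99)
  expect_identical(b1, b2)

  one <- abundances(50)
  b0 <- bootstrap_envelope(one, function(s) zeta_estimate(s, 1), B = 200, seed = 1)
  expect_equal(b0$upper - b0$lower, 0)
  expect_error(bootstrap_envelope(smp, stat, B = 50), class = "gsimpson_domain_error")

  # coverage of the true Hurlbert index across repeated samples: the
  # percentile interval runs close to, but a little below, nominal here
  # (resampling from p-hat recentres the interval at the plug-in value)
  comm <- make_community("uniform", 10)
  truth <- hurlbert_index(comm, 20)
  set.seed(321)
  reps <- 100
  cover <- vapply(seq_len(reps), function(i) {
    s <- sample_community(comm, 500)
    env <- bootstrap_envelope(s, stat, B = 300)
    env$lower <= truth && truth <= env$upper
  }, logical(1))
  phat <- mean(cover)
  expect_gt(phat, 0.78)
  expect_lte(phat, 1)
})
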