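test_that("Z_r reproduces hand-derived and degenerate values", {
  # one species: the j = 1 factor is (1 - (n-1)/(n-1)) = 0
  expect_equal(zeta_estimate(5, 1:4), rep(0, 4))
  # all singletons: every factor is 1
  expect_equal(zeta_estimate(c(1, 1, 1, 1), 1:3), rep(1, 3))
  expect_equal(zeta_estimate(c(2, 1), 1), 2 / 3)
  expect_equal(zeta_estimate(c(2, 2), 2), 1 / 3)
  expect_error(zeta_estimate(c(2, 1), 3), class = "gsimpson_invalid_order")
})

test_that("Z_r agrees with the factorial form of the estimator", {
  set.seed(99)
  for (i in 1:20) {
    smp <- sample_community(random_community(sample(2:8, 1)),
                            n = sample(5:40, 1))
    n <- sum(smp$count)
    for (r in unique(c(1, 2, min(5, n - 1)))) {
      expect_equal(zeta_estimate(smp, r), oracle_z_factorial(smp$count, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("Z_r is exactly unbiased under iid sampling (independent enumeration)", {
  for (comm in list(community(c(2 / 3, 1 / 3)), community(c(0.5, 0.3, 0.2)))) {
    p <- comm$prob
    for (n in 2:5) {
      for (r in seq_len(n - 1)) {
        ez <- oracle_expectation_iid(p, n, function(cnt) {
          zeta_estimate(cnt, r)
        })
        expect_equal(ez, zeta(comm, r), tolerance = 1e-12)
      }
    }
  }
})

test_that("Z_1 equals the sum n_s (n - n_s) / (n (n-1)) identity", {
  set.seed(5)
  for (i in 1:10) {
    smp <- sample_community(random_community(6), n = 50)
    n <- sum(smp$count)
    expect_equal(zeta_estimate(smp, 1),
                 sum(smp$count * (n - smp$count)) / (n * (n - 1)))
  }
})

test_that("Z_r stays in [0, 1] across random samples and orders", {
  set.seed(13)
  for (i in 1:30) {
    smp <- sample_community(random_community(sample(2:15, 1)),
                            n = sample(3:60, 1))
    n <- sum(smp$count)
    vals <- zeta_estimate(smp, seq_len(n - 1))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("sigma-hat matches hand delta-method values and degenerate rules", {
  expect_equal(suppressWarnings(zeta_se(c(3, 3, 3), 1)), 0)
  expect_warning(zeta_se(c(3, 3, 3), 1), class = "gsimpson_degenerate_warning")
  expect_error(zeta_se(7, 1), class = "gsimpson_undefined_variance")
  # p-hat = (0.6, 0.4), r = 1: sigma = 0.4 * sqrt(0.24)
  expect_equal(zeta_se(c(60, 40), 1), sqrt(0.4^2 * 0.24), tolerance = 1e-12)
})

test_that("sigma-hat is invariant to which species is listed last", {
  set.seed(21)
  smp <- sample_community(random_community(7), n = 120)
  base <- zeta_se(smp, 2)
  for (i in 1:5) {
    perm <- sample(nrow(smp))
    permuted <- abundances(smp$count[perm], labels = smp$species[perm])
    expect_equal(zeta_se(permuted, 2), base, tolerance = 1e-12)
  }
})

test_that("confidence intervals combine Z, sigma and the normal quantile", {
  # counts with p-hat = (0.6, 0.4), n = 100: Z_1 = 0.48 by the Z_1 identity
  ci <- zeta_ci(c(60, 40), 1, alpha = 0.05)
  expect_equal(ci$estimate, sum(c(60, 40) * c(40, 60)) / (100 * 99))
  half <- qnorm(0.975) * ci$sigma / 10
  expect_equal(ci$lower, ci$estimate - half)
  expect_equal(ci$upper, ci$estimate + half)
  expect_equal(ci$level, 0.95)

  # degenerate interval when sigma-hat = 0
  ci0 <- suppressWarnings(zeta_ci(c(2, 2), 1))
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)

  # clamping: all-singleton sample has Z = 1, upper must stay at 1
  ci1 <- suppressWarnings(zeta_ci(rep(1, 6), 2))
  expect_lte(ci1$upper, 1)
  expect_gte(ci1$lower, 0)
})

test_that("entropy profiles track the closed form for a uniform community", {
  expect_equal(suppressWarnings(zeta_profile(rep(1, 4), max_order = 3))$estimate,
               rep(1, 3))
  expect_error(zeta_profile(c(2, 2), max_order = 4),
               class = "gsimpson_invalid_order")

  comm <- make_community("uniform", 20)
  smp <- sample_community(comm, n = 200, seed = 31)
  prof <- suppressWarnings(zeta_profile(smp, max_order = 19))
  n <- 200
  for (r in prof$order) {
    bound <- 3 * max(prof$sigma[r], 0.05) / sqrt(n)
    expect_lt(abs(prof$estimate[r] - (1 - 1 / 20)^r), max(bound, 0.06))
  }
})

test_that("diversity profiles are the monotone image of entropy profiles", {
  smp <- sample_community(make_community("geometric", 12, 0.6), 300, seed = 17)
  ent <- zeta_profile(smp, max_order = 8, scale = "entropy")
  div <- zeta_profile(smp, max_order = 8, scale = "diversity")
  for (r in 1:8) {
    expect_equal(div$estimate[r], effective_number(ent$estimate[r], r))
    expect_equal(div$lower[r], effective_number(ent$lower[r], r))
    expect_equal(div$upper[r], effective_number(ent$upper[r], r))
  }
  # all-singleton sample: infinite diversity at every order
  d <- suppressWarnings(zeta_profile(rep(1, 5), max_order = 3, scale = "diversity"))
  expect_true(all(is.infinite(d$estimate)))
  # Z_1 = 0.5 -> 2 effective species
  expect_equal(effective_number(0.5, 1), 2)
})

test_that("profiles flag orders beyond the estimated richness bound", {
  smp <- sample_community(make_community("geometric", 8, 0.5), 400, seed = 3)
  rich <- jackknife_richness(smp, order = 1)
  expect_warning(
    prof <- zeta_profile(smp, max_order = 15, richness = rich),
    class = "gsimpson_order_warning"
  )
  expect_true(all(prof$valid[prof$order <= max_valid_order(rich)]))
  expect_false(any(prof$valid[prof$order > max_valid_order(rich)]))
})

test_that("automatic max order uses the jackknife richness bound", {
  smp <- sample_community(make_community("geometric", 10, 0.7), 500, seed = 8)
  prof <- zeta_profile(smp)
  rich <- jackknife_richness(smp)
  expect_equal(max(prof$order), min(sum(smp$count) - 1, max_valid_order(rich)))
})
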