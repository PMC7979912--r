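test_that("simulation is deterministic and exact in the noiseless limit", {
  p <- growthParams(v = 0.3, k_stall = 0, k_term = 0)
  s1 <- simulateRibbons(p, c(1, 2, 4), n_ribbons = 25, rng_seed = 5)
  s2 <- simulateRibbons(p, c(1, 2, 4), n_ribbons = 25, rng_seed = 5)
  expect_identical(s1, s2)
  expect_equal(s1$length_nm, 0.3 * s1$time_h * 3600)
  expect_error(simulateRibbons(p, c(2, 1), 10), "increasing")
  expect_error(growthParams(v = -1), "non-negative")
})

test_that("the analytic mean matches its limits and the simulation", {
  p <- fastGrowthParams()
  expect_equal(analyticMeanLength(p, 0)$mean_nm, 0)
  # kTerm -> 0 limit reduces to vEff * t
  p0 <- growthParams(v = 0.25, k_stall = 2e-4, k_resume = 2e-3, k_term = 0)
  am0 <- analyticMeanLength(p0, c(1, 4))
  expect_equal(am0$mean_nm, effectiveVelocity(p0) * c(1, 4) * 3600)
  # law of large numbers: sample mean within 3 SE at n = 1e4
  tm <- c(1, 2, 4, 8, 16)
  sim <- simulateRibbons(p, tm, n_ribbons = 1e4, rng_seed = 42)
  am <- analyticMeanLength(p, tm)
  for (i in seq_along(tm)) {
    x <- sim$length_nm[sim$time_h == tm[i]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - am$mean_nm[i]), 3 * se)
  }
  # long-time mean approaches vEff / kTerm
  simL <- simulateRibbons(p, 24 * 7, n_ribbons = 1e4, rng_seed = 43)
  x <- simL$length_nm
  expect_lt(abs(mean(x) - effectiveVelocity(p) / p@kTerm),
            3 * stats::sd(x) / sqrt(length(x)))
})

test_that("mean length is monotone in time and termination rate", {
  p <- fastGrowthParams()
  am <- analyticMeanLength(p, seq(0.5, 24, by = 0.5))
  expect_true(all(diff(am$mean_nm) > 0))
  ks <- c(1e-6, 1e-5, 1e-4, 1e-3)
  means <- vapply(ks, function(k)
    analyticMeanLength(growthParams(v = 0.25, k_term = k), 8)$mean_nm,
    numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("fitting recovers exact parameters from noiseless analytic means", {
  p <- growthParams(v = 0.22, k_stall = 0, k_term = 2e-5)
  tm <- c(1, 2, 4, 8, 25)
  am <- analyticMeanLength(p, tm)
  samples <- data.frame(condition = "exact", time_h = rep(tm, each = 4),
                        length_nm = rep(am$mean_nm, each = 4))
  fit <- fitGrowthModel(samples, n_boot = 0)
  expect_equal(unname(fit@estimates["vEff"]), 0.22, tolerance = 1e-6)
  expect_equal(unname(fit@estimates["kTerm"]), 2e-5, tolerance = 1e-6)
  expect_error(fitGrowthModel(samples[samples$time_h == 1, ]),
               "3 distinct timepoints")
  samples$length_nm <- 0
  expect_error(fitGrowthModel(samples), "zero")
})

test_that("polydispersity index behaves as the weight/number-average ratio", {
  expect_equal(polydispersityIndex(rep(7, 20)), 1)
  set.seed(21)
  x <- stats::rexp(2e5)
  expect_equal(polydispersityIndex(x), 2, tolerance = 0.05)
  expect_error(polydispersityIndex(numeric(0)), "non-empty")
  expect_error(polydispersityIndex(c(0, 0)), "zero")
  expect_error(polydispersityIndex(c(-1, 2)), "non-negative")
})

test_that("seeded growth is less polydisperse than spontaneous nucleation", {
  p <- fastGrowthParams()
  seeded <- simulateRibbons(p, 8, n_ribbons = 1e4, rng_seed = 8)
  unseeded <- simulateRibbons(p, 8, n_ribbons = 1e4, rng_seed = 8,
                              nucleation = "poisson")
  pdiS <- polydispersityIndex(seeded$length_nm)
  pdiU <- polydispersityIndex(unseeded$length_nm[unseeded$length_nm > 0])
  expect_lt(pdiS, pdiU)
})

test_that("velocity and rate constant convert both ways", {
  expect_equal(rateConstantFromVelocity(0.75, 1e-6, 1.5), 0.5e6)
  expect_equal(rateConstantFromVelocity(0, 1e-6), 0)
  k <- rateConstantFromVelocity(0.334, 5e-7, 1.5)
  expect_equal(velocityFromRateConstant(k, 5e-7, 1.5), 0.334,
               tolerance = 1e-12)
  expect_error(rateConstantFromVelocity(0.5, 0), "positive")
})

test_that("ribbon copy number tracks the seeds", {
  expect_equal(ribbonCountFromSeeds(2e-9, 1), 2e-9)
  expect_equal(ribbonCountFromSeeds(2e-9, 0), 0)
  expect_equal(ribbonCountFromSeeds(1e-9, 0.5),
               ribbonCountFromSeeds(2e-9, 0.5) / 2)
  expect_error(ribbonCountFromSeeds(2e-9, 1.2), "\\[0, 1\\]")
})
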