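test_that("the worked detection-limit arithmetic chain is self-consistent", {
  # 5 um ribbons at 1.5 nm/slat -> ~3300 slats (2 s.f.)
  slats <- slatsPerRibbon(5000, 1.5)
  expect_equal(as.numeric(slats), 3300)
  expect_equal(attr(slats, "exact"), 5000 / 1.5)
  expect_equal(as.numeric(slatsPerRibbon(1.5, 1.5)), 1)
  expect_equal(attr(slatsPerRibbon(4000, 1.5), "exact"), 8000 / 3)
  # half a million ribbons in 4 uL -> ~200 fM
  conc <- ribbonsToMolar(5e5, 4)
  expect_equal(conc, 2.08e-13, tolerance = 0.01)
  expect_equal(ribbonsToMolar(0, 4), 0)
  # 200 fM over 100 h -> ~0.6 aM/s
  rate <- nucleationRateEndpoint(200e-15, 100)
  expect_equal(rate, 0.56e-18, tolerance = 0.01)
  expect_equal(nucleationRateEndpoint(0, 100), 0)
  expect_equal(nucleationRateEndpoint(200e-15, 50), 2 * rate)
  # mass of that population ~ 60 pg, near the ~65 pg detection floor
  mass <- ribbonMass(ribbonSpec(5000, 1.5, slat_nt = 66), 5e5)
  expect_gt(mass, 45e-12)
  expect_lt(mass, 80e-12)
  expect_equal(ribbonMass(ribbonSpec(), 0), 0)
  expect_equal(ribbonMass(ribbonSpec(slat_nt = 132), 1e5),
               2 * ribbonMass(ribbonSpec(slat_nt = 66), 1e5))
})

test_that("unit conversions are exact inverses", {
  for (conc in c(2.1e-13, 2e-9, 5e-7)) {
    expect_equal(ribbonsToMolar(molarToRibbons(conc, 4), 4), conc,
                 tolerance = 1e-12)
  }
  expect_equal(molarToRibbons(ribbonsToMolar(12345, 7.5), 7.5), 12345,
               tolerance = 1e-12)
})

test_that("gel quantification recovers the ribbon concentration ratio", {
  lanes <- gelLanes(role = c("seeded_control", "unseeded"),
                    intensity = c(1000, 1000), seed_conc = c(2e-9, NA),
                    duration_h = 10)
  res <- unseededRateFromGel(lanes)
  expect_false(res$censored)
  expect_equal(res$ribbon_conc, 2e-9)
  expect_equal(res$rate, 2e-9 / (10 * 3600))
  # half the intensity, half the concentration
  lanes2 <- lanes; lanes2$intensity[2] <- 500
  expect_equal(unseededRateFromGel(lanes2)$ribbon_conc, 1e-9)
  expect_error(unseededRateFromGel(lanes[2, ]), "seeded_control")
  lanes3 <- lanes; lanes3$intensity[1] <- 0
  expect_error(unseededRateFromGel(lanes3), "control intensity")
})

test_that("sub-floor lanes always yield censored bounds, never estimates", {
  lanes <- gelLanes(role = c("seeded_control", "unseeded"),
                    intensity = c(1000, 1e-5), seed_conc = c(2e-9, NA),
                    duration_h = 12)
  res <- unseededRateFromGel(lanes, floor_conc = 200e-15)
  expect_true(res$censored)
  expect_true(is.na(res$rate))
  expect_equal(res$upper_bound, 200e-15 / (12 * 3600))
  # censoring property across a sweep of intensities around the floor
  for (i in c(1e-6, 1e-3, 0.05, 0.09)) {
    lanes$intensity[2] <- i
    r <- unseededRateFromGel(lanes, floor_conc = 200e-15)
    impliedConc <- i / 1000 * 2e-9
    if (impliedConc < 200e-15) {
      expect_true(r$censored)
      expect_true(is.na(r$rate))
    } else {
      expect_false(r$censored)
      expect_equal(r$ribbon_conc, impliedConc, tolerance = 1e-9)
    }
  }
})

test_that("synthetic gel lanes round-trip the true nucleation rate", {
  trueJ <- 5e-18
  lanes <- synthGelDataset(trueJ, nucleation_h = 12, noise_sd = 0.02,
                           rng_seed = 4)
  res <- unseededRateFromGel(lanes, nucleation_h = 12)
  expect_false(res$censored)
  expect_equal(res$rate, trueJ, tolerance = 0.10)
  # zero true rate: unseeded lane must come out censored
  lanes0 <- synthGelDataset(0, nucleation_h = 12, rng_seed = 4)
  res0 <- unseededRateFromGel(lanes0, nucleation_h = 12)
  expect_true(res0$censored)
})
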