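test_that("best-first search agrees with exhaustive enumeration on small assemblies", {
  # quick cross-check at modest size; the full three-architecture sweep to
  # 8 monomers is in the acceptance suite
  arch <- architecture("CS", n = 2)
  p <- calibratedParams(arch, eps = 1)
  oracle <- enumerateBarriers(arch, p, 6)
  bf <- vapply(1:6, function(s) minimaxBarrier(arch, p, s)$barrier,
               numeric(1))
  expect_equal(bf, oracle, tolerance = 1e-12)
})

test_that("the CS staircase pathway is the minimal-barrier pathway", {
  for (n in 2:3) {
    arch <- architecture("CS", n = n)
    p <- calibratedParams(arch, eps = 1.5)
    exact <- criticalNucleus(arch, p, max_size = 2 * n + 2, method = "exact")
    stair <- criticalNucleus(arch, p, max_size = 2 * n + 2,
                             method = "staircase")
    expect_equal(barrier(stair), barrier(exact), tolerance = 1e-9)
  }
})

test_that("a chain of n = 1 slats peaks at the first monomer when bonds beat cost", {
  arch <- architecture("CS", n = 1)
  p <- ktamParams(1, gMC = 3, gSE = 4)   # gSE > gMC: every addition downhill
  l <- criticalNucleus(arch, p, max_size = 4, method = "exact")
  expect_equal(barrier(l), 3)
  expect_equal(criticalSize(l), 1L)
  expect_equal(max(enumerateBarriers(arch, p, 4)), 3)
})

test_that("the near-reversible CS critical nucleus is n y-slats plus n x-slats", {
  arch <- architecture("CS", n = 6)
  p <- ktamParams(arch, epsilon = 1e-6, concentration = 1e-6)
  l <- criticalNucleus(arch, p, max_size = 16)
  expect_equal(criticalSize(l), 12L)
  expect_equal(barrier(l), 6 * gMC(p), tolerance = 1e-4)
})

test_that("an unbracketed profile is reported as an error", {
  arch <- architecture("CS", n = 6)
  p <- calibratedParams(arch)
  expect_error(criticalNucleus(arch, p, max_size = 6), "unbracketed")
})

test_that("barriers and critical sizes shrink with irreversibility", {
  arch <- architecture("CS", n = 6)
  p <- calibratedParams(arch, eps = 0)
  for (m in c("analytic", "staircase")) {
    cur <- barrierVsEpsilon(arch, p, seq(0, 3, length.out = 31), method = m)
    expect_true(all(diff(cur$barrier) <= 1e-9))
    expect_true(all(diff(cur$critical_size) <= 1e-9))
    expect_gte(cur$barrier[1], cur$barrier[cur$epsilon == 2][1])
  }
  expect_error(barrierVsEpsilon(arch, p, c(2, 1)), "increasing")
})

test_that("the barrier slope in epsilon is -B*/n where the nucleus is constant", {
  arch <- architecture("CS", n = 6)
  p <- calibratedParams(arch, eps = 0)
  eps <- seq(1.8, 2.2, by = 0.01)
  cur <- barrierVsEpsilon(arch, p, eps, method = "staircase")
  const <- cur$critical_size == cur$critical_size[1]
  expect_true(all(const))
  l <- criticalNucleus(arch, ktamParams(6, epsilon = 2, gMC = p@gMC),
                       max_size = 16, method = "staircase")
  Bstar <- l@bondsAtCritical
  slopes <- diff(cur$barrier) / diff(cur$epsilon)
  expect_equal(slopes, rep(-Bstar / 6, length(slopes)), tolerance = 1e-6)
})

test_that("architectures can be matched at the reversible limit", {
  cs6 <- architecture("CS", n = 6)
  p0 <- ktamParams(cs6, epsilon = 0, concentration = 1e-6)
  B0 <- reversibleBarrier(cs6, gMC(p0))
  st <- matchArchitectures(cs6, p0, architecture("ST", circumference = 2))
  expect_equal(st$arch@circumference, 11L)
  expect_lt(abs(reversibleBarrier(st$arch, gMC(st$params)) - B0), 1e-6)
  ht <- matchArchitectures(cs6, p0, architecture("HT", circumference = 2))
  expect_lt(abs(reversibleBarrier(ht$arch, gMC(ht$params)) - B0), 1e-6)
  # matching an architecture to itself changes nothing
  self <- matchArchitectures(cs6, p0, cs6)
  expect_equal(gMC(self$params), gMC(p0))
  expect_equal(gSE(self$params), gSE(p0))
  expect_error(
    matchArchitectures(cs6, p0, architecture("ST", circumference = 2),
                       max_circumference = 1),
    "no feasible match")
})

test_that("a matched tile reversible barrier is reproduced by the exact search", {
  # small enough system for the discrete search to verify the closed form:
  # CS n=2 reference matches an ST tube of circumference 3
  cs2 <- architecture("CS", n = 2)
  p0 <- ktamParams(cs2, epsilon = 0, gMC = 3)
  st <- matchArchitectures(cs2, p0, architecture("ST", circumference = 2))
  expect_equal(st$arch@circumference, 3L)
  found <- minimaxBarrier(st$arch, st$params, 10)$barrier
  expect_equal(found, reversibleBarrier(cs2, 3), tolerance = 1e-9)
})

test_that("the seed pre-pays the nucleation barrier", {
  arch <- architecture("CS", n = 6)
  p <- calibratedParams(arch, eps = 2)
  seeded <- landscapeWithSeed(arch, p)
  # first capture on a fully nucleator-occupied seed: dG = gMC - n gSE = -eps
  expect_equal(seeded@pathway$dG[1], -2, tolerance = 1e-12)
  # every steady-state addition lowers G by eps decades
  tailSteps <- tail(seeded@pathway$dG, 12)
  expect_equal(tailSteps, rep(-2, 12), tolerance = 1e-12)
  post <- seeded@Gprofile[-seq_len(1)]
  expect_true(all(diff(seeded@Gprofile) <= 1e-12))
  unseeded <- criticalNucleus(arch, p, max_size = 16)
  expect_gte(barrier(unseeded), max(seeded@Gprofile))
  expect_error(landscapeWithSeed(architecture("ST", circumference = 4), p),
               "CS")
})

test_that("calibrated analytic barriers order the architectures correctly", {
  g <- gMC(ktamParams(2, epsilon = 2, concentration = 1e-6))
  bST <- analyticBarrier(architecture("ST", circumference = 11),
                         ktamParams(2, epsilon = 2, gMC = g))$barrier
  bHT <- analyticBarrier(architecture("HT", circumference = 9),
                         ktamParams(3, epsilon = 2, gMC = g))$barrier
  bCS6 <- analyticBarrier(architecture("CS", n = 6),
                          ktamParams(6, epsilon = 2, gMC = g))$barrier
  bCS8 <- analyticBarrier(architecture("CS", n = 8),
                          ktamParams(8, epsilon = 2, gMC = g))$barrier
  expect_true(bCS8 > bCS6 && bCS6 > bHT && bHT > bST)
})
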