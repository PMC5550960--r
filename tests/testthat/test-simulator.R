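test_that("traction map generation is deterministic and respects the spec", {
  spec <- simulationSpec(gridShape = c(96, 96), footprintRange = c(6, 10),
                         areaRange = c(0.25, 6))
  m1 <- generateTractionMap(spec, seed = 7)
  m2 <- generateTractionMap(spec, seed = 7)
  expect_identical(xComp(m1$tractions), xComp(m2$tractions))
  expect_identical(m1$footprints, m2$footprints)
  m3 <- generateTractionMap(spec, seed = 8)
  expect_false(identical(xComp(m1$tractions), xComp(m3$tractions)))
  # footprint count within the requested range (rounded to pairs)
  expect_gte(nrow(m1$footprints), 6)
  expect_lte(nrow(m1$footprints), 10)
  # peaks and areas within the sampled ranges
  expect_true(all(m1$footprints$peak_Pa >= 600 & m1$footprints$peak_Pa <= 4000))
  expect_true(all(m1$footprints$area_um2 >= 0.25 & m1$footprints$area_um2 <= 6))
  # contractile pairs balance exactly
  expect_lt(abs(sum(xComp(m1$tractions))), 1e-8)
  expect_lt(abs(sum(yComp(m1$tractions))), 1e-8)
})

test_that("a single requested footprint has the requested peak and area", {
  spec <- simulationSpec(gridShape = c(96, 96), directionMode = "random")
  m <- generateTractionMap(spec, seed = 11, n = 1, balanceNet = FALSE)
  expect_identical(nrow(m$footprints), 1L)
  mag <- fieldMagnitude(m$tractions)
  expect_equal(max(mag), m$footprints$peak_Pa, tolerance = 0.01)
  # support area within one pixel-ring of the requested footprint area
  h <- 0.32
  npix <- sum(mag >= 0.5 * max(mag))
  rpix <- sqrt(m$footprints$area_um2 / h^2 / pi)
  ring <- pi * ((rpix + 1)^2 - (rpix - 1)^2)
  expect_lt(abs(npix - m$footprints$area_um2 / h^2), ring)
})

test_that("random-direction maps are globally balanced on demand", {
  spec <- simulationSpec(gridShape = c(96, 96), footprintRange = c(6, 10),
                         areaRange = c(0.25, 6), directionMode = "random")
  m <- generateTractionMap(spec, seed = 19)
  expect_lt(abs(sum(xComp(m$tractions))), 1e-8)
  expect_lt(abs(sum(yComp(m$tractions))), 1e-8)
  m2 <- generateTractionMap(spec, seed = 19, balanceNet = FALSE)
  expect_gt(abs(sum(xComp(m2$tractions))) + abs(sum(yComp(m2$tractions))), 1)
})

test_that("an overcrowded grid fails with a placement error", {
  spec <- simulationSpec(gridShape = c(32, 32), footprintRange = c(40, 40),
                         areaRange = c(10, 20))
  expect_error(generateTractionMap(spec, seed = 1), "crowded|fit")
})

test_that("noisy displacements follow the noise model", {
  spec <- simulationSpec(gridShape = c(128, 128), footprintRange = c(6, 10),
                         areaRange = c(0.25, 6))
  map <- generateTractionMap(spec, seed = 3)
  # zero noise returns the ideal field exactly
  u0 <- generateNoisyDisplacements(map$tractions, spec@substrate,
                                   noiseSigma = 0, seed = 5)
  expect_identical(xComp(u0$noisy), xComp(u0$ideal))
  # empirical sigma within 5% of the requested value on a 128 x 128 field
  u <- generateNoisyDisplacements(map$tractions, spec@substrate,
                                  noiseSigma = 0.02, seed = 5)
  expect_equal(sd(xComp(u$noisy) - xComp(u$ideal)), 0.02, tolerance = 0.05)
  expect_equal(sd(yComp(u$noisy) - yComp(u$ideal)), 0.02, tolerance = 0.05)
  # same ideal component, different noise under another seed
  u2 <- generateNoisyDisplacements(map$tractions, spec@substrate,
                                   noiseSigma = 0.02, seed = 6)
  expect_identical(xComp(u2$ideal), xComp(u$ideal))
  expect_false(identical(xComp(u2$noisy), xComp(u$noisy)))
  # the default sigma implements the 10%-of-median rule
  ud <- generateNoisyDisplacements(map$tractions, spec@substrate, seed = 5)
  magI <- fieldMagnitude(ud$ideal)
  expect_equal(ud$sigma, 0.1 * median(magI[magI > 0]))
})

test_that("noiseless recovery at small lambda reproduces the simulation", {
  spec <- simulationSpec(gridShape = c(64, 64), footprintRange = c(4, 4),
                         areaRange = c(1, 4), peakRange = c(1, 3),
                         noiseSigma = 0)
  case <- simulateCase(spec, seed = 23)
  rs <- segmentDisplacementRegions(case$noisy, dilationRadius = 4)
  for (scheme in c("l2_spatial", "l1")) {
    cfg <- regConfig(scheme, lambda = 1e-4, irlsMaxIter = 40L,
                     tractionUnit = "kPa")
    res <- suppressWarnings(solveReduced(case$noisy, spec@substrate, cfg, rs))
    rep <- metricsReport(tractions(res), case$tractions, spec@substrate)
    expect_lt(rep$e_m, 5)
    expect_lt(rep$e_a, 5)
    expect_equal(rep$LFA, 0)
  }
})

test_that("the benchmark emits one fully populated row per scheme", {
  spec <- simulationSpec(gridShape = c(64, 64), footprintRange = c(4, 6),
                         areaRange = c(0.5, 4))
  tab <- suppressWarnings(
    runBenchmark(spec, lambdas = c(l2_spatial = 0.2), nCases = 1, seed = 2,
                 nRealizations = 1, irlsMaxIter = 10L))
  expect_identical(nrow(tab), 1L)
  expect_true(all(c("e_m", "e_a", "e_A", "LFA", "SFA", "net_pct",
                    "coverage_pct", "scheme", "case") %in% names(tab)))
  expect_true(is.finite(tab$coverage_pct))
  expect_identical(tab$scheme, "l2_spatial")
})
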