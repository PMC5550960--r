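test_that("spatial L2 reproduces ridge-regression closed forms", {
  # identity operator, lambda = 1: t = u / 2
  u <- c(3, -1, 2)
  r <- solveL2Spatial(diag(3), u, regConfig("l2_spatial", lambda = 1))
  expect_equal(tractions(r), u / 2)
  expect_identical(iterations(r), 1L)
  # lambda = 0 with invertible K: exact inverse
  set.seed(1)
  K <- diag(4) + 0.1 * matrix(rnorm(16), 4)
  u <- rnorm(4)
  r0 <- solveL2Spatial(K, u, regConfig("l2_spatial", lambda = 0))
  expect_equal(as.vector(solve(K, u)), tractions(r0), tolerance = 1e-8)
  # lambda = 0 with rank-deficient K: explicit error
  Ksing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(solveL2Spatial(Ksing, c(1, 2),
                              regConfig("l2_spatial", lambda = 0)),
               "singular")
  # dimension mismatch is rejected
  expect_error(solveL2Spatial(diag(4), c(1, 2), regConfig("l2_spatial")),
               "inconsistent")
})

test_that("spatial L2 matches an augmented least-squares oracle", {
  set.seed(42)
  K <- matrix(rnorm(400), 20)
  u <- rnorm(20)
  lam <- 0.2
  r <- solveL2Spatial(K, u, regConfig("l2_spatial", lambda = lam))
  aug <- qr.solve(rbind(K, sqrt(lam) * diag(20)), c(u, numeric(20)))
  expect_equal(tractions(r), as.vector(aug), tolerance = 1e-8)
})

test_that("IRLS penalty weights implement the L1 majorizer", {
  expect_equal(irlsPenaltyWeights(c(2, -4)), c(0.5, 0.25))
  # zero entries are floored, not infinite
  w <- irlsPenaltyWeights(c(1, 0), eps = 1e-8)
  expect_equal(w[2], 1e8)
  # majorizer identity: t' W t at t = t_prev equals ||t_prev||_1
  set.seed(3)
  t <- rnorm(50)
  w <- irlsPenaltyWeights(t)
  expect_equal(sum(w * t^2), sum(abs(t)), tolerance = 1e-10)
})

test_that("L1 IRLS starts from the L2 solution and soft-thresholds for K = I", {
  u <- c(3, 0.05, -2)
  cfg1 <- regConfig("l1", lambda = 0.1, irlsMaxIter = 1L)
  r1 <- suppressWarnings(solveL1IRLS(diag(3), u, cfg1))
  rl2 <- solveL2Spatial(diag(3), u, regConfig("l2_spatial", lambda = 0.1))
  expect_equal(tractions(r1), tractions(rl2))
  # the fixed point for K = I is elementwise soft-thresholding at lambda
  # (sub-threshold entries collapse to the eps floor)
  r <- solveL1IRLS(diag(3), u, regConfig("l1", lambda = 0.1))
  expect_true(converged(r))
  expect_equal(tractions(r)[1], 2.9, tolerance = 0.02)
  expect_equal(tractions(r)[3], -1.9, tolerance = 0.02)
  expect_lt(abs(tractions(r)[2]), 1e-4)
})

test_that("L1 IRLS recovers the support of sparse tractions", {
  sub <- gel()
  tf <- toy_traction(24, two = TRUE)
  u <- forwardDisplacements(tf, sub)
  pts <- gridPoints(c(24, 24))
  K <- assembleStiffness(pts, pts, sub)
  cfg <- regConfig("l1", lambda = 1e-4, irlsMaxIter = 40L,
                   tractionUnit = "kPa")
  r <- suppressWarnings(solveL1IRLS(K, c(xComp(u), yComp(u)), cfg))
  t <- tractions(r)
  truth <- c(xComp(tf), yComp(tf))
  peak <- max(abs(truth))
  # no spurious tractions above 1% of peak outside the true support
  expect_lt(max(abs(t[truth == 0])), 0.01 * peak)
  # true footprints survive
  expect_gt(max(abs(t[truth != 0])), 0.5 * peak)
})

test_that("full-L1 IRLS solves the elementwise 1D problem for K = I", {
  u <- c(3, 0.5, -2)
  # lambda < 1: fidelity dominates, minimiser of |t-u| + lam|t| is t = u
  r <- suppressWarnings(
    solveFullL1IRLS(diag(3), u, regConfig("full_l1", lambda = 0.5)))
  expect_equal(tractions(r), u, tolerance = 1e-4)
  # lambda > 1: penalty dominates, t = 0
  r2 <- suppressWarnings(
    solveFullL1IRLS(diag(3), u, regConfig("full_l1", lambda = 2)))
  expect_lt(max(abs(tractions(r2))), 1e-4)
  # first iteration with W = W_d = I is the L2 solution
  r3 <- suppressWarnings(
    solveFullL1IRLS(diag(3), u, regConfig("full_l1", lambda = 0.5,
                                          irlsMaxIter = 1L)))
  expect_equal(tractions(r3),
               tractions(solveL2Spatial(diag(3), u,
                                        regConfig("l2_spatial", lambda = 0.5))))
})

test_that("IRLS objective is non-increasing across iterations", {
  set.seed(9)
  K <- matrix(rnorm(30 * 20), 30)
  u <- rnorm(30)
  for (scheme in c("l1", "full_l1")) {
    cfg <- regConfig(scheme, lambda = 0.5, irlsMaxIter = 60L)
    r <- suppressWarnings(
      if (scheme == "l1") solveL1IRLS(K, u, cfg) else
        solveFullL1IRLS(K, u, cfg))
    tr <- r@objectiveTrace
    expect_true(all(diff(tr) <= 1e-8 * max(abs(tr))),
                label = paste(scheme, "objective descent"))
  }
})

test_that("solution norm shrinks monotonically with lambda (L2)", {
  set.seed(5)
  K <- matrix(rnorm(200), 20)
  u <- rnorm(20)
  norms <- vapply(c(0.01, 0.05, 0.2, 1, 5), function(lam) {
    r <- solveL2Spatial(K, u, regConfig("l2_spatial", lambda = lam))
    sqrt(sum(tractions(r)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("Fourier L2 handles limits and matches the spatial solution", {
  sub <- gel()
  n <- 32
  z <- DisplacementField(matrix(0, n, n), matrix(0, n, n), 0.32)
  r0 <- solveL2Fourier(z, sub, regConfig("l2_fourier", lambda = 1e-3))
  expect_equal(max(fieldMagnitude(tractions(r0))), 0)
  # tractions confined to the central quarter; padded transform agrees
  # with the dense spatial solve to < 2% of peak
  tx <- gauss_bump(n, 16, 17, 2.2, 800); tx[tx < 40] <- 0
  tf <- TractionField(tx, 0.5 * tx, 0.32)
  u <- forwardDisplacements(tf, sub)
  pts <- gridPoints(c(n, n))
  K <- assembleStiffness(pts, pts, sub)
  for (lam in c(0.01, 0.1)) {
    rF <- solveL2Fourier(u, sub, regConfig("l2_fourier", lambda = lam))
    rS <- solveL2Spatial(K, c(xComp(u), yComp(u)),
                         regConfig("l2_spatial", lambda = lam))
    dif <- max(abs(c(xComp(tractions(rF)), yComp(tractions(rF))) -
                     tractions(rS)))
    expect_lt(dif, 0.02 * max(abs(tractions(rS))))
  }
  # over-regularization kills the solution
  rBig <- solveL2Fourier(u, sub, regConfig("l2_fourier", lambda = 1e9))
  expect_lt(max(fieldMagnitude(tractions(rBig))),
            1e-6 * max(fieldMagnitude(tf)))
  # noiseless forward-inverse round trip at small lambda recovers the
  # footprint interior (kPa units: lambda is negligible there)
  rRT <- solveL2Fourier(u, sub, regConfig("l2_fourier", lambda = 1e-6,
                                          tractionUnit = "kPa"))
  inside <- tx > 0.5 * max(tx)
  relerr <- sqrt(sum((xComp(tractions(rRT))[inside] - tx[inside])^2) /
                   sum(tx[inside]^2))
  expect_lt(relerr, 0.05)
})

test_that("lambda search selects by the requested criterion", {
  set.seed(12)
  K <- matrix(rnorm(200), 20)
  tstar <- c(rep(0, 7), 3, -2, rep(0, 1))
  u <- as.vector(K %*% tstar)   # noiseless
  # single-value grid returns that value
  one <- lambdaSearch(K, u, "l2_spatial", lamGrid = 0.3)
  expect_equal(one$lambda, 0.3)
  # with ground truth and noiseless data the smallest lambda wins
  res <- lambdaSearch(K, u, "l2_spatial", lamGrid = c(0.01, 0.1, 0.5),
                      groundTruth = tstar)
  expect_equal(res$lambda, 0.01)
  expect_identical(res$criterion, "ground_truth")
  expect_true(all(diff(res$table$gt_error) > 0))
  # without ground truth the cost functional is reported for every lambda
  res2 <- lambdaSearch(K, u, "l2_spatial", lamGrid = c(0.05, 0.2))
  expect_identical(res2$criterion, "cost")
  expect_true(all(is.finite(res2$table$cost)))
})

test_that("L1 schemes give sparser fields and full-L1 lowers the data fidelity", {
  sub <- gel()
  spec <- simulationSpec(gridShape = c(48, 48), footprintRange = c(4, 4),
                         areaRange = c(0.5, 3), peakRange = c(1, 3))
  case <- simulateCase(spec, seed = 55)
  u <- case$noisy
  K <- assembleStiffness(gridPoints(c(48, 48)), substrate = sub)
  uv <- c(xComp(u), yComp(u))
  sol <- list()
  for (scheme in c("l2_spatial", "l1", "full_l1")) {
    lam <- c(l2_spatial = 0.2, l1 = 0.08, full_l1 = 0.1)[[scheme]]
    cfg <- regConfig(scheme, lambda = lam, irlsMaxIter = 25L,
                     tractionUnit = "kPa")
    sol[[scheme]] <- suppressWarnings(switch(scheme,
      l2_spatial = solveL2Spatial(K, uv, cfg),
      l1 = solveL1IRLS(K, uv, cfg),
      full_l1 = solveFullL1IRLS(K, uv, cfg)))
  }
  sparsity <- vapply(sol, function(r) {
    t <- tractions(r)
    mean(abs(t) < 0.01 * max(abs(t)))
  }, numeric(1))
  expect_gte(sparsity[["l1"]], sparsity[["l2_spatial"]])
  expect_gte(sparsity[["full_l1"]], sparsity[["l2_spatial"]])
  # full-L1 reduces the L1 data-fidelity term relative to L1 at matched
  # lambda
  expect_lt(sol[["full_l1"]]@residualL1, sol[["l1"]]@residualL1)
})
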