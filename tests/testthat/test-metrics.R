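# builds a matched pair of footprint sets from two traction fields
match_fixture <- function(tHat, tGt, sub = gel()) {
  fpH <- extractFootprints(fieldMagnitude(tHat) > 0, tHat, sub)
  fpG <- extractFootprints(fieldMagnitude(tGt) > 0, tGt, sub)
  list(m = matchFootprints(fpH, fpG), fpH = fpH, fpG = fpG)
}

test_that("magnitude error scales with the relative perturbation", {
  tGt <- toy_traction(32, two = TRUE)
  fx <- match_fixture(tGt, tGt)
  expect_equal(magnitudeError(fx$m, tGt, tGt, fx$fpG), 0)
  tUp <- TractionField(1.1 * xComp(tGt), 1.1 * yComp(tGt), 0.32)
  fx2 <- match_fixture(tUp, tGt)
  expect_equal(magnitudeError(fx2$m, tUp, tGt, fx2$fpG), 10, tolerance = 1e-9)
  # brute-force oracle on a random perturbation
  set.seed(8)
  px <- xComp(tGt) * (1 + 0.2 * runif(length(xComp(tGt))))
  tP <- TractionField(px, yComp(tGt), 0.32)
  fx3 <- match_fixture(tP, tGt)
  magH <- fieldMagnitude(tP); magG <- fieldMagnitude(tGt)
  per <- vapply(seq_len(nrow(fx3$m$pairs)), function(i) {
    p <- footprintPixels(fx3$fpG)[[fx3$m$pairs$gt[i]]]
    100 * sum(abs(magH[p] - magG[p])) / sum(magG[p])
  }, numeric(1))
  expect_equal(magnitudeError(fx3$m, tP, tGt, fx3$fpG), mean(per))
  expect_equal(magnitudeError(fx3$m, tP, tGt, fx3$fpG, "as_printed"),
               sum(per))
})

test_that("angle error is the magnitude-weighted angle over 180 degrees", {
  tGt <- toy_traction(32)
  fx <- match_fixture(tGt, tGt)
  expect_equal(angleError(fx$m, tGt, tGt, fx$fpG), 0)
  # 90-degree rotation: 50%
  rot <- TractionField(-yComp(tGt), xComp(tGt), 0.32)
  fxr <- match_fixture(rot, tGt)
  expect_equal(angleError(fxr$m, rot, tGt, fxr$fpG), 50, tolerance = 1e-9)
  # anti-parallel: the 180-degree cap gives 100%
  anti <- TractionField(-xComp(tGt), -yComp(tGt), 0.32)
  fxa <- match_fixture(anti, tGt)
  expect_equal(angleError(fxa$m, anti, tGt, fxa$fpG), 100, tolerance = 1e-9)
})

test_that("area error compares matched footprint areas", {
  sub <- gel()
  tx <- matrix(0, 32, 32); tx[4:8, 4:8] <- 900       # 25 px
  gx <- matrix(0, 32, 32); gx[4:8, 4:8] <- 900
  gx[20:23, 20:24] <- 700                             # second footprint
  tx[20:23, 20:24] <- 700
  tGt <- TractionField(gx, 0 * gx, 0.32)
  tHat <- TractionField(tx, 0 * tx, 0.32)
  fx <- match_fixture(tHat, tGt)
  expect_equal(areaError(fx$m, fx$fpH, fx$fpG), 0)
  # inflate one recovered footprint by 20% of its area (25 -> 30 px)
  tx2 <- tx; tx2[9, 4:8] <- 900
  tB <- TractionField(tx2, 0 * tx2, 0.32)
  fx2 <- match_fixture(tB, tGt)
  expect_equal(areaError(fx2$m, fx2$fpH, fx2$fpG), mean(c(20, 0)))
})

test_that("loss ratio and smallest detectable footprint follow their formulas", {
  expect_equal(lossRatio(10, 10), 0)
  expect_equal(lossRatio(10, 7), 30)
  expect_equal(lossRatio(10, 0), 100)
  expect_error(lossRatio(10, 11))
  expect_equal(smallestDetectable(0.25, 0.68), 0.17)
  expect_equal(smallestDetectable(0.38, 0.89), 0.3382)
  expect_equal(min(smallestDetectable(c(1, 1, 1), c(0.17, 0.29, 2))), 0.17)
})

test_that("net traction balance sums components and normalizes by the peak", {
  # equal and opposite point tractions cancel exactly
  tx <- matrix(0, 16, 16); tx[4, 4] <- 500; tx[12, 12] <- -500
  b <- netTractionBalance(TractionField(tx, 0 * tx, 0.32))
  expect_equal(b$sum_x, 0); expect_equal(b$pct_of_max, 0)
  z <- netTractionBalance(TractionField(matrix(0, 4, 4), matrix(0, 4, 4), 0.32))
  expect_equal(unlist(z), c(sum_x = 0, sum_y = 0, pct_of_max = 0))
  set.seed(4)
  rx <- matrix(rnorm(64), 8); ry <- matrix(rnorm(64), 8)
  b2 <- netTractionBalance(TractionField(rx, ry, 0.32))
  expect_equal(b2$sum_x, sum(rx))
  expect_equal(b2$pct_of_max,
               100 * max(abs(sum(rx)), abs(sum(ry))) / max(sqrt(rx^2 + ry^2)))
})

test_that("metrics are invariant under joint translation and a report assembles", {
  sub <- gel()
  tGt <- toy_traction(48, two = TRUE)
  shift <- function(f) {
    sx <- matrix(0, 48, 48); sy <- matrix(0, 48, 48)
    sx[6:48, 6:48] <- xComp(f)[1:43, 1:43]
    sy[6:48, 6:48] <- yComp(f)[1:43, 1:43]
    TractionField(sx, sy, 0.32)
  }
  tHat <- TractionField(1.15 * xComp(tGt), 1.15 * yComp(tGt), 0.32)
  fx <- match_fixture(tHat, tGt)
  fxs <- match_fixture(shift(tHat), shift(tGt))
  expect_equal(magnitudeError(fx$m, tHat, tGt, fx$fpG),
               magnitudeError(fxs$m, shift(tHat), shift(tGt), fxs$fpG))
  expect_equal(areaError(fx$m, fx$fpH, fx$fpG),
               areaError(fxs$m, fxs$fpH, fxs$fpG))
  # a full report on perfect recovery: all errors zero
  rep <- metricsReport(tGt, tGt, sub)
  expect_equal(rep$e_m, 0); expect_equal(rep$e_a, 0)
  expect_equal(rep$e_A, 0); expect_equal(rep$LFA, 0)
  expect_identical(rep$n_spurious, 0L)
  expect_gte(rep$SFA, 0)
})

test_that("metrics refuse empty matches", {
  tGt <- toy_traction(32)
  empty <- list(pairs = data.frame(recovered = integer(), gt = integer(),
                                   overlap_px = integer()),
                spurious = integer(), lost = 1L, nMatchedGT = 0L)
  fpG <- extractFootprints(fieldMagnitude(tGt) > 0, tGt, gel())
  expect_error(magnitudeError(empty, tGt, tGt, fpG), "no matched")
  expect_error(smallestDetectable(numeric(), numeric()))
})
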