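# Shared fixtures: a soft-gel substrate matching a typical TFM experiment
# (5 kPa polyacrylamide, nu = 0.45, 0.32 um pixels) and small synthetic
# fields built in code.

gel <- function() Substrate(youngModulus = 5000, poissonRatio = 0.45,
                            pixelSpacing = 0.32)

# single Gaussian bump magnitude on an n x n grid
gauss_bump <- function(n, r0, c0, sigma, peak = 1) {
  d2 <- outer((seq_len(n) - r0)^2, (seq_len(n) - c0)^2, "+")
  peak * exp(-d2 / (2 * sigma^2))
}

# a small traction field with one or two compact footprints
toy_traction <- function(n = 32, two = FALSE, peak = 1000, spacing = 0.32) {
  tx <- gauss_bump(n, n %/% 3, n %/% 3, 1.6, peak)
  tx[tx < 0.5 * peak] <- 0
  ty <- 0.5 * tx
  if (two) {
    b <- gauss_bump(n, 2 * n %/% 3 + 1, 2 * n %/% 3, 1.6, peak)
    b[b < 0.5 * peak] <- 0
    tx <- tx - b          # second footprint pulls the other way
    ty <- ty - 0.5 * b
  }
  TractionField(tx, ty, spacing)
}

# brute-force midpoint quadrature of the Boussinesq kernel over a source
# pixel (independent oracle for stiffness entries)
kernel_quad_oracle <- function(drow, dcol, sub, nq = 300) {
  h <- sub@pixelSpacing
  E <- sub@youngModulus; nu <- sub@poissonRatio
  C <- (1 + nu) / (pi * E)
  s <- seq(-h / 2 + h / nq / 2, h / 2 - h / nq / 2, length.out = nq)
  w <- (h / nq)^2
  dx <- dcol * h - rep(s, each = nq)   # x offsets (columns)
  dy <- drow * h - rep(s, times = nq)
  r2 <- dx^2 + dy^2; r <- sqrt(r2); r3 <- r2 * r
  list(xx = sum(C * ((1 - nu) / r + nu * dx^2 / r3)) * w,
       xy = sum(C * nu * dx * dy / r3) * w,
       yy = sum(C * ((1 - nu) / r + nu * dy^2 / r3)) * w)
}
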