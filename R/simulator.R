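## Synthetic benchmark generator.
##
## Emulates the simulated cases used to compare the regularization
## schemes: a sparse map of stress footprints (random positions,
## directions, peaks and areas), forward displacements through the
## Boussinesq model, and additive Gaussian noise on the displacement
## components standing in for displacement-estimation error. Footprints
## are truncated Gaussian blobs whose width is calibrated so that the
## 2-level isodata footprint mask of an isolated blob covers the requested
## area. Because adherent cells are in mechanical equilibrium, footprint
## directions are adjusted so the net traction of each map is zero.

# evaluate fn with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# Footprints are Gaussian peaks truncated at half maximum: the support is
# the full-width-at-half-maximum disk, whose area is the requested
# footprint area, and the edge is sharp -- like a stress footprint cut out
# of a recovered field at the most restrictive isodata threshold.
# area = pi * r_half^2 with r_half^2 = 2 sigma^2 ln 2:
.sigma_for_area <- function(areaPx) sqrt(areaPx / (2 * pi * log(2)))
.halfmax_radius <- function(sigma) sigma * sqrt(2 * log(2))

#' Generate a sparse ground-truth traction map
#'
#' Places `n` non-overlapping stress footprints at random positions, each
#' a compact blob (truncated Gaussian by default, or a uniform disk) with
#' a peak magnitude, area and direction drawn from the spec's ranges
#' (areas log-uniform, peaks and directions uniform). With
#' `balanceNet = TRUE` (default) and at least two footprints, directions
#' are adjusted and a final magnitude-weighted correction applied so the
#' map's net traction is exactly zero, as for a cell in mechanical
#' equilibrium.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed integer seed; identical spec + seed give bit-identical
#'   output.
#' @param n optional fixed footprint count (default: drawn uniformly from
#'   `spec@footprintRange`).
#' @param balanceNet enforce zero net traction (default TRUE).
#' @param maxTries placement retries per footprint before giving up.
#' @return list with `tractions` (a [VectorField2D-class] in Pa) and
#'   `footprints` (data.frame: row, col, peak_Pa, area_um2, sigma_px,
#'   theta).
#' @export
generateTractionMap <- function(spec, seed, n = NULL, balanceNet = TRUE,
                                maxTries = 500L) {
  validObject(spec)
  .with_seed(seed, function() {
    dims <- spec@gridShape
    h <- spec@substrate@pixelSpacing
    if (is.null(n))
      n <- sample(seq(spec@footprintRange[1], spec@footprintRange[2]), 1)
    paired <- spec@directionMode == "paired" && n >= 2
    if (paired) n <- 2L * (n %/% 2L)  # pairs need an even count
    if (paired) {
      # one size/peak per pair, shared by both members
      np <- n %/% 2L
      areas <- rep(exp(stats::runif(np, log(spec@areaRange[1]),
                                    log(spec@areaRange[2]))), each = 2)
      peaks <- rep(stats::runif(np, spec@peakRange[1],
                                spec@peakRange[2]) * 1000, each = 2)
      axes <- stats::runif(np, 0, 2 * pi)
      # members pull toward each other along the pair axis
      thetas <- as.vector(rbind(axes, axes + pi)) %% (2 * pi)
    } else {
      areas <- exp(stats::runif(n, log(spec@areaRange[1]),
                                log(spec@areaRange[2])))
      peaks <- stats::runif(n, spec@peakRange[1], spec@peakRange[2]) * 1000
      thetas <- stats::runif(n, 0, 2 * pi)
    }
    sigmas <- .sigma_for_area(areas / h^2)
    cut <- .halfmax_radius(sigmas)
    ctr <- (dims + 1) / 2
    cellR <- spec@cellFraction * min(dims) / 2
    rows <- cols <- numeric(n)
    place_one <- function(i, anchor = NULL) {
      # anchor: for the second pair member, the position of the first,
      # offset along the pair axis so the truncated skirts nearly touch
      m <- ceiling(cut[i]) + 1L
      if (2 * m >= min(dims))
        stop("footprint ", i, " does not fit on the grid")
      for (try in seq_len(maxTries)) {
        if (is.null(anchor)) {
          r0 <- sample(seq(m + 1L, dims[1] - m), 1)
          c0 <- sample(seq(m + 1L, dims[2] - m), 1)
        } else {
          # second member sits where the first one pulls toward, at a
          # stress-fiber-like separation of 8-16 um
          d <- max(stats::runif(1, 8, 16) / h, cut[i] + cut[i - 1L] + 4)
          r0 <- round(anchor[1] + d * sin(thetas[i - 1L]))
          c0 <- round(anchor[2] + d * cos(thetas[i - 1L]))
          if (r0 <= m || r0 > dims[1] - m || c0 <= m || c0 > dims[2] - m)
            return(NULL)
        }
        if ((r0 - ctr[1])^2 + (c0 - ctr[2])^2 > cellR^2) {
          if (is.null(anchor)) next else return(NULL)
        }
        ok <- TRUE
        if (i > 1L) {
          # footprints must stay separable after recovery smearing
          j <- seq_len(i - 1L)
          dmin <- cut[i] + cut[j] + 6
          ok <- all((r0 - rows[j])^2 + (c0 - cols[j])^2 > dmin^2)
        }
        if (ok) return(c(r0, c0))
        if (!is.null(anchor)) return(NULL)
      }
      NULL
    }
    i <- 1L
    while (i <= n) {
      second <- paired && i %% 2L == 0L
      pos <- NULL
      if (second) {
        for (try in seq_len(50L)) {
          pos <- place_one(i, anchor = c(rows[i - 1L], cols[i - 1L]))
          if (!is.null(pos)) break
          # re-draw the pair axis and re-place the first member
          thetas[c(i - 1L, i)] <- (stats::runif(1, 0, 2 * pi) +
                                     c(0, pi)) %% (2 * pi)
          p1 <- place_one(i - 1L)
          if (is.null(p1))
            stop("could not place footprint ", i - 1L, " of ", n,
                 " after ", maxTries, " tries; the grid is too crowded")
          rows[i - 1L] <- p1[1]; cols[i - 1L] <- p1[2]
        }
      } else {
        pos <- place_one(i)
      }
      if (is.null(pos))
        stop("could not place footprint ", i, " of ", n,
             " after ", maxTries, " tries; the grid is too crowded")
      rows[i] <- pos[1]; cols[i] <- pos[2]
      i <- i + 1L
    }
    # render footprints
    mag <- tx <- ty <- matrix(0, dims[1], dims[2])
    patches <- vector("list", n)
    for (i in seq_len(n)) {
      m <- ceiling(cut[i])
      rr <- (rows[i] - m):(rows[i] + m)
      cc <- (cols[i] - m):(cols[i] + m)
      d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, "+")
      p <- if (spec@footprintShape == "gaussian") {
        peaks[i] * exp(-d2 / (2 * sigmas[i]^2))
      } else {
        peaks[i] * (d2 <= areas[i] / h^2 / pi)
      }
      p[d2 > cut[i]^2] <- 0
      patches[[i]] <- list(rr = rr, cc = cc, p = p)
      mag[rr, cc] <- mag[rr, cc] + p
    }
    dirs <- cbind(cos(thetas), sin(thetas))
    if (!paired && balanceNet && n >= 2) {
      f <- vapply(patches, function(q) sum(q$p), numeric(1))
      for (it in seq_len(200)) {
        FF <- colSums(dirs * f)
        if (sqrt(sum(FF^2)) / sum(f) < 1e-4) break
        v <- dirs - matrix(FF / sum(f), n, 2, byrow = TRUE)
        dirs <- v / sqrt(rowSums(v^2))
      }
    }
    for (i in seq_len(n)) {
      q <- patches[[i]]
      tx[q$rr, q$cc] <- tx[q$rr, q$cc] + q$p * dirs[i, 1]
      ty[q$rr, q$cc] <- ty[q$rr, q$cc] + q$p * dirs[i, 2]
    }
    if (!paired && balanceNet && n >= 2) {
      # exact zero net traction: distribute the small residual over the
      # support, weighted by magnitude
      w <- mag / sum(mag)
      tx <- tx - w * sum(tx)
      ty <- ty - w * sum(ty)
    }
    list(tractions = TractionField(tx, ty, h),
         footprints = data.frame(row = rows, col = cols, peak_Pa = peaks,
                                 area_um2 = areas, sigma_px = sigmas,
                                 theta = thetas))
  })
}

#' Noisy displacements from a ground-truth traction field
#'
#' Computes the ideal displacements through the forward Boussinesq model
#' and adds i.i.d. zero-mean Gaussian noise to each component, standing in
#' for the error of displacement estimation from bead images.
#'
#' @param tGt ground-truth traction [VectorField2D-class].
#' @param substrate a [Substrate-class].
#' @param noiseSigma noise standard deviation in um; NA (default) uses 10%
#'   of the median nonzero ideal displacement magnitude.
#' @param seed integer seed for the noise.
#' @return list with `ideal` and `noisy` displacement
#'   [VectorField2D-class] fields and the `sigma` used (um).
#' @export
generateNoisyDisplacements <- function(tGt, substrate,
                                       noiseSigma = NA_real_, seed = 1L) {
  uIdeal <- forwardDisplacements(tGt, substrate)
  mag <- fieldMagnitude(uIdeal)
  sigma <- if (is.na(noiseSigma))
    0.1 * stats::median(mag[mag > 0]) else noiseSigma
  noisy <- .with_seed(seed, function() {
    dims <- dim(uIdeal@x)
    DisplacementField(
      uIdeal@x + matrix(stats::rnorm(prod(dims), 0, sigma), dims[1]),
      uIdeal@y + matrix(stats::rnorm(prod(dims), 0, sigma), dims[1]),
      substrate@pixelSpacing)
  })
  if (sigma == 0) noisy <- uIdeal
  list(ideal = uIdeal, noisy = noisy, sigma = sigma)
}

#' Simulate one complete synthetic case
#'
#' @param spec a [SimulationSpec-class].
#' @param seed integer case seed.
#' @param realization realization index (changes only the noise).
#' @param n optional fixed footprint count.
#' @return list: `tractions`, `footprints`, `ideal`, `noisy`,
#'   `noiseSigma`, `seed`, `realization`.
#' @export
simulateCase <- function(spec, seed, realization = 1L, n = NULL) {
  map <- generateTractionMap(spec, seed, n = n)
  u <- generateNoisyDisplacements(map$tractions, spec@substrate,
                                  spec@noiseSigma,
                                  seed = seed + as.integer(realization))
  list(tractions = map$tractions, footprints = map$footprints,
       ideal = u$ideal, noisy = u$noisy, noiseSigma = u$sigma,
       seed = seed, realization = realization)
}

#' Run the synthetic comparison benchmark
#'
#' For every case and noise realization: simulate a ground-truth map,
#' segment the noisy displacement magnitude (Otsu) for the
#' stiffness-matrix reduction, recover tractions with each scheme at its
#' lambda, extract and match stress footprints (2-level isodata), and
#' compute all error metrics.
#'
#' @param spec a [SimulationSpec-class].
#' @param lambdas named numeric vector mapping scheme names (any of
#'   "l2_fourier", "l2_spatial", "l1", "full_l1") to their regularization
#'   parameter.
#' @param nCases number of synthetic cases (traction maps).
#' @param seed master seed; case and realization seeds are derived from
#'   it deterministically.
#' @param nRealizations noise realizations per case (default from spec).
#' @param irlsMaxIter IRLS iteration cap for the L1 schemes.
#' @param dilationRadius,memoryLimit passed to the reduction.
#' @param verbose print per-case progress.
#' @return data.frame, one row per case x realization x scheme, with the
#'   error metrics, footprint counts, mask coverage (% of displacement
#'   magnitude kept) and net-traction balance. Failed cases are dropped
#'   with a warning naming the case.
#' @export
runBenchmark <- function(spec,
                         lambdas = c(l2_spatial = 0.2, l1 = 0.08,
                                     full_l1 = 0.1),
                         nCases = 10L, seed = 1L,
                         nRealizations = spec@nRealizations,
                         irlsMaxIter = 30L,
                         dilationRadius = 4L, memoryLimit = 2e9,
                         verbose = FALSE) {
  stopifnot(nCases >= 1, length(lambdas) >= 1, !is.null(names(lambdas)))
  rows <- list()
  for (ci in seq_len(nCases)) {
    caseSeed <- (seed + 7919L * ci) %% .Machine$integer.max
    out <- tryCatch({
      map <- generateTractionMap(spec, caseSeed)
      tGt <- map$tractions
      fpGt <- extractFootprints(footprintMask(tGt, "metrics_2level"),
                                tGt, spec@substrate)
      caseRows <- list()
      for (ri in seq_len(nRealizations)) {
        u <- generateNoisyDisplacements(tGt, spec@substrate,
                                        spec@noiseSigma,
                                        seed = caseSeed + ri)
        regions <- segmentDisplacementRegions(u$noisy, dilationRadius)
        cov <- maskCoverage(u$noisy, regions)
        for (scheme in names(lambdas)) {
          cfg <- regConfig(scheme, lambda = lambdas[[scheme]],
                           irlsMaxIter = irlsMaxIter,
                           tractionUnit = "kPa")
          res <- suppressWarnings(
            if (scheme == "l2_fourier")
              solveL2Fourier(u$noisy, spec@substrate, cfg)
            else
              solveReduced(u$noisy, spec@substrate, cfg, regions,
                           memoryLimit = memoryLimit))
          tHat <- res@tractions
          rep <- metricsReport(tHat, tGt, spec@substrate)
          rep$case <- ci; rep$realization <- ri
          rep$scheme <- scheme; rep$lambda <- lambdas[[scheme]]
          rep$coverage_pct <- cov
          rep$noise_sigma_um <- u$sigma
          rep$n_footprints_nominal <- nrow(map$footprints)
          rep$iterations <- res@iterations
          rep$converged <- res@converged
          caseRows[[length(caseRows) + 1L]] <- rep
        }
        if (verbose)
          message(sprintf("case %d realization %d done", ci, ri))
      }
      do.call(rbind, caseRows)
    }, error = function(e) {
      warning(sprintf("case %d failed: %s", ci, conditionMessage(e)))
      NULL
    })
    if (!is.null(out)) rows[[length(rows) + 1L]] <- out
  }
  if (!length(rows)) stop("every benchmark case failed")
  do.call(rbind, rows)
}
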