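## Stiffness-matrix reduction.
##
## A full-field spatial-domain solve is intractable for microscope-sized
## grids: the dense stiffness matrix for an 800 x 800 field needs
## 2N * 2M * 8 bytes ~ 13 TB. Cells, however, exert tractions at discrete
## sites (clusters of focal adhesions), and the displacement signal decays
## quickly away from them, so the inverse problem can be restricted to the
## high-displacement regions: Otsu-threshold the displacement magnitude,
## label the disjoint regions, solve a small dense problem per region with
## N = M = the region's pixels, and recombine into the full field (zero
## tractions outside the mask).

#' Otsu threshold of a scalar image
#'
#' Classical Otsu threshold on a 256-bin histogram: the cut maximizing the
#' between-class variance of the two resulting classes.
#'
#' @param magnitude nonnegative finite numeric matrix or vector, not all
#'   equal.
#' @param nBins number of histogram bins (default 256).
#' @return the threshold value (same units as the input); values >=
#'   threshold form the foreground class.
#' @export
otsuThreshold <- function(magnitude, nBins = 256L) {
  v <- as.numeric(magnitude)
  stopifnot(all(is.finite(v)), all(v >= 0))
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("cannot threshold a constant image")
  width <- (hi - lo) / nBins
  counts <- tabulate(pmin(floor((v - lo) / width) + 1L, nBins), nBins)
  p <- counts / length(v)
  centers <- lo + (seq_len(nBins) - 0.5) * width
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  # between-class variance for a cut after bin k (k = 1..nBins-1)
  k <- seq_len(nBins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigmaB <- ifelse(denom > 0, (muT * omega[k] - mu[k])^2 / denom, -Inf)
  best <- which.max(sigmaB)
  lo + best * width  # upper edge of the last background bin
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 8-connected labeling: 4-connected pass (EBImage) then merge labels that
# touch diagonally
.label8 <- function(mask) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    unique(cbind(a[keep], b[keep]))
  }
  # diagonal neighbor pairs (down-right and down-left)
  pairs <- rbind(
    merge_pairs(lab[-nr, -nc], lab[-1, -1]),
    merge_pairs(lab[-nr, -1], lab[-1, -nc]))
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- .uf_find(parent, pairs[i, 1])
      rb <- .uf_find(parent, pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

# drop small components and relabel contiguously
.prune_relabel <- function(lab, minSize) {
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  if (!length(keep)) return(matrix(0L, nrow(lab), ncol(lab)))
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Segment high-displacement regions
#'
#' Thresholds the displacement magnitude with Otsu's method, optionally
#' dilates the mask (a generous segmentation keeps displacement tails),
#' labels 8-connected components and removes tiny ones. The resulting
#' disjoint regions drive the stiffness-matrix reduction.
#'
#' @param u a displacement [VectorField2D-class].
#' @param dilationRadius disc dilation radius in pixels (default 2; 0
#'   reproduces the plain Otsu mask).
#' @param minRegionSize smallest component kept, in pixels (default 4).
#' @return a [RegionSet-class].
#' @export
segmentDisplacementRegions <- function(u, dilationRadius = 2L,
                                       minRegionSize = 4L) {
  validObject(u)
  mag <- fieldMagnitude(u)
  thr <- otsuThreshold(mag)
  mask <- mag >= thr
  if (dilationRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilationRadius) + 1L, "disc")
    mask <- EBImage::dilate(mask * 1L, brush) > 0
  }
  lab <- .label8(mask)
  lab <- .prune_relabel(lab, minRegionSize)
  n <- max(lab)
  if (n == 0L)
    stop("segmentation produced no usable regions; ",
         "review the noise level and the regularization parameter")
  pix <- split(which(lab > 0L), lab[lab > 0L])
  new("RegionSet", labelImage = lab, regionCount = as.integer(n),
      pixels = unname(pix))
}

#' Fraction of displacement magnitude inside a region mask
#'
#' @param u a displacement [VectorField2D-class].
#' @param regions a [RegionSet-class] on the same grid.
#' @return percentage of the total displacement magnitude retained inside
#'   the labeled regions.
#' @export
maskCoverage <- function(u, regions) {
  mag <- fieldMagnitude(u)
  100 * sum(mag[regions@labelImage > 0L]) / sum(mag)
}

#' Memory footprint of a dense stiffness matrix
#'
#' Size in bytes of the dense 2N x 2M double-precision stiffness matrix:
#' 2N * 2M * 8. For a full 800 x 800 field (N = M = 640000) this is about
#' 13 terabytes, which is why the reduction exists.
#'
#' @param N,M numbers of observation and source points.
#' @return bytes, as a double.
#' @examples
#' memoryEstimate(800^2, 800^2)  # ~1.3e13
#' @export
memoryEstimate <- function(N, M) {
  stopifnot(N >= 1, M >= 1)
  2 * as.numeric(N) * 2 * as.numeric(M) * 8
}

#' Solve the inverse problem per segmented region
#'
#' Applies a spatial-domain scheme independently to every disjoint region:
#' N = M = the region's pixels, a local stiffness matrix is assembled and
#' solved, and the recovered tractions are written back at the region's
#' pixels (zero everywhere else), preserving the full field size.
#'
#' @param u a displacement [VectorField2D-class].
#' @param substrate a [Substrate-class].
#' @param cfg a [RegularizationConfig-class] with a spatial-domain scheme.
#' @param regions a [RegionSet-class] from
#'   [segmentDisplacementRegions()].
#' @param memoryLimit refuse to assemble a local stiffness matrix larger
#'   than this many bytes (default 2 GB).
#' @return a [SolveResult-class] whose `tractions` is a full-field
#'   [VectorField2D-class] in Pa; iteration counts and norms are summed
#'   over regions.
#' @export
solveReduced <- function(u, substrate, cfg, regions,
                         memoryLimit = 2e9) {
  validObject(u); validObject(substrate)
  if (cfg@scheme == "l2_fourier")
    stop("the Fourier path needs the full grid; use solveL2Fourier")
  dims <- dim(u@x)
  tx <- matrix(0, dims[1], dims[2])
  ty <- matrix(0, dims[1], dims[2])
  iterations <- 0L
  convergedAll <- TRUE
  res2 <- res1 <- pen2sq <- pen1 <- obj <- 0
  for (r in seq_len(regions@regionCount)) {
    pix <- regions@pixels[[r]]
    n <- length(pix)
    est <- memoryEstimate(n, n)
    if (est > memoryLimit)
      stop(sprintf(
        "region %d has %d pixels; its stiffness matrix needs %.3g bytes (limit %.3g)",
        r, n, est, memoryLimit))
    pts <- arrayInd(pix, dims)
    K <- assembleStiffness(pts, pts, substrate)
    uvec <- c(u@x[pix], u@y[pix])
    res <- .solve_spatial(K, uvec, cfg)
    t <- res@tractions
    tx[pix] <- t[seq_len(n)]
    ty[pix] <- t[n + seq_len(n)]
    iterations <- iterations + res@iterations
    convergedAll <- convergedAll && res@converged
    res2 <- res2 + res@residualL2^2
    res1 <- res1 + res@residualL1
    pen2sq <- pen2sq + res@penaltyL2^2
    pen1 <- pen1 + res@penaltyL1
    obj <- obj + utils::tail(res@objectiveTrace, 1)
  }
  new("SolveResult",
      tractions = TractionField(tx, ty, substrate@pixelSpacing),
      iterations = iterations, converged = convergedAll,
      residualL2 = sqrt(res2), residualL1 = res1,
      penaltyL2 = sqrt(pen2sq), penaltyL1 = pen1, objectiveTrace = obj)
}
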