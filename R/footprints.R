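## Stress-footprint segmentation and matching.
##
## Stress footprints -- connected regions of high traction magnitude,
## standing in for clusters of focal adhesions -- are segmented by
## multilevel isodata thresholding of the traction magnitude: 5 levels
## (keeping the most restrictive) when synthesizing ground-truth masks,
## 2 levels (keeping the larger) when evaluating recovered fields.

#' Multilevel isodata thresholds
#'
#' Iterative cluster-mean thresholding. With one level this is the
#' classical isodata algorithm (the threshold converges to the midpoint of
#' the two class means); with n levels, n thresholds partition the values
#' into n + 1 classes and each threshold is iterated to the midpoint of
#' the adjacent class means until the assignment stabilizes.
#'
#' @param magnitude non-constant finite numeric vector or matrix.
#' @param nLevels number of thresholds (>= 1).
#' @param maxIter,tol iteration controls.
#' @return strictly increasing numeric vector of `nLevels` thresholds.
#' @examples
#' isodataThresholds(c(0, 0, 0, 10, 10, 10), 1)  # 5
#' @export
isodataThresholds <- function(magnitude, nLevels = 2L, maxIter = 200L,
                              tol = 1e-10) {
  v <- as.numeric(magnitude)
  stopifnot(all(is.finite(v)), nLevels >= 1)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("cannot threshold a constant image")
  thr <- unname(stats::quantile(v, seq_len(nLevels) / (nLevels + 1)))
  # guard degenerate quantile starts
  thr <- pmin(pmax(thr, lo + 1e-12 * (hi - lo)), hi - 1e-12 * (hi - lo))
  thr <- sort(thr)
  for (it in seq_len(maxIter)) {
    cls <- findInterval(v, thr)          # 0..nLevels
    means <- vapply(0:nLevels, function(k) {
      x <- v[cls == k]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
    # an empty class inherits the midpoint of its bounding thresholds
    if (anyNA(means)) {
      bounds <- c(lo, thr, hi)
      for (k in which(is.na(means)))
        means[k] <- (bounds[k] + bounds[k + 1]) / 2
    }
    newThr <- (means[-length(means)] + means[-1]) / 2
    newThr <- sort(newThr)
    if (max(abs(newThr - thr)) < tol * (hi - lo)) {
      thr <- newThr
      break
    }
    thr <- newThr
  }
  if (any(diff(thr) <= 0))
    stop("isodata thresholds collapsed; the image may be near-constant")
  thr
}

#' Binary stress-footprint mask of a traction field
#'
#' Thresholds the traction magnitude at the most restrictive multilevel
#' isodata threshold: the largest of 5 in `synthesis_5level_top` mode
#' (used to create ground-truth footprint masks) or the larger of 2 in
#' `metrics_2level` mode (used to extract footprints from recovered
#' fields before computing error metrics).
#'
#' @param t a traction [VectorField2D-class].
#' @param mode "synthesis_5level_top" or "metrics_2level".
#' @return logical matrix; all-FALSE for an all-zero field.
#' @export
footprintMask <- function(t, mode = c("metrics_2level",
                                      "synthesis_5level_top")) {
  mode <- match.arg(mode)
  validObject(t)
  mag <- fieldMagnitude(t)
  if (max(mag) == 0) return(matrix(FALSE, nrow(mag), ncol(mag)))
  n <- if (mode == "synthesis_5level_top") 5L else 2L
  thr <- max(isodataThresholds(mag, n))
  mag >= thr
}

#' Extract labeled stress footprints
#'
#' Labels the 8-connected components of a footprint mask and tabulates
#' per-footprint area (pixel count times the squared pixel spacing), peak
#' traction magnitude and centroid.
#'
#' @param mask logical matrix, same shape as the traction field.
#' @param t a traction [VectorField2D-class].
#' @param substrate a [Substrate-class] (provides the pixel spacing).
#' @return a [FootprintSet-class].
#' @export
extractFootprints <- function(mask, t, substrate) {
  validObject(t)
  if (!identical(dim(mask), dim(t@x)))
    stop("mask shape does not match the traction field")
  h <- substrate@pixelSpacing
  lab <- .label8(mask)
  n <- max(lab)
  mag <- fieldMagnitude(t)
  if (n == 0L) {
    return(new("FootprintSet",
               table = data.frame(label = integer(), n_pixels = integer(),
                                  area_um2 = numeric(), peak_Pa = numeric(),
                                  centroid_row = numeric(),
                                  centroid_col = numeric()),
               pixels = list(), fieldDim = dim(mask)))
  }
  pix <- unname(split(which(lab > 0L), lab[lab > 0L]))
  rows <- lapply(seq_len(n), function(k) {
    p <- pix[[k]]
    rc <- arrayInd(p, dim(mask))
    data.frame(label = k, n_pixels = length(p),
               area_um2 = length(p) * h^2,
               peak_Pa = max(mag[p]),
               centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]))
  })
  new("FootprintSet", table = do.call(rbind, rows), pixels = pix,
      fieldDim = dim(mask))
}

#' Match recovered footprints to ground truth
#'
#' Pairs every recovered footprint with the ground-truth footprint of
#' maximal pixel overlap (ties broken toward the larger ground-truth
#' footprint). Recovered footprints with zero overlap are spurious;
#' ground-truth footprints never matched are lost.
#'
#' @param recovered,groundTruth [FootprintSet-class] objects on the same
#'   grid.
#' @return list with `pairs` (data.frame: recovered, gt, overlap_px),
#'   `spurious` (recovered labels), `lost` (ground-truth labels), and
#'   `nMatchedGT` (distinct ground-truth footprints recovered).
#' @export
matchFootprints <- function(recovered, groundTruth) {
  if (!identical(recovered@fieldDim, groundTruth@fieldDim))
    stop("footprint sets come from different grid shapes")
  npx <- prod(recovered@fieldDim)
  gtLab <- integer(npx)
  for (k in seq_along(groundTruth@pixels))
    gtLab[groundTruth@pixels[[k]]] <- k
  gtSize <- groundTruth@table$n_pixels
  pairs <- list(); spurious <- integer()
  for (k in seq_along(recovered@pixels)) {
    labs <- gtLab[recovered@pixels[[k]]]
    labs <- labs[labs > 0L]
    if (!length(labs)) {
      spurious <- c(spurious, k)
      next
    }
    ov <- table(labs)
    cand <- as.integer(names(ov))[ov == max(ov)]
    best <- cand[which.max(gtSize[cand])]
    pairs[[length(pairs) + 1L]] <-
      data.frame(recovered = k, gt = best, overlap_px = max(ov))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(recovered = integer(), gt = integer(),
               overlap_px = integer())
  lost <- setdiff(seq_along(groundTruth@pixels), pairs$gt)
  list(pairs = pairs, spurious = spurious, lost = lost,
       nMatchedGT = length(unique(pairs$gt)))
}
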