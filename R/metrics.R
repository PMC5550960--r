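## Error metrics for recovered traction fields.
##
## All footprint-wise metrics are evaluated over the pixels P_n of the
## ground-truth footprint associated with each recovered footprint, and
## aggregated as the mean over recovered footprints (an "as_printed" mode
## sums the per-footprint percentages instead, which exceeds 100% as soon
## as several footprints are present).

.check_match <- function(match) {
  if (nrow(match$pairs) == 0)
    stop("no matched footprints; the metric is undefined")
}

#' Error in recovered traction magnitude
#'
#' Per matched footprint, the absolute magnitude error summed over the
#' associated ground-truth footprint pixels, normalized by the summed
#' ground-truth magnitude, times 100.
#'
#' @param match result of [matchFootprints()].
#' @param tHat,tGt recovered and ground-truth traction
#'   [VectorField2D-class] fields.
#' @param groundTruth the ground-truth [FootprintSet-class] (supplies the
#'   pixel sets P_n).
#' @param aggregate "mean" (default) averages the per-footprint
#'   percentages; "as_printed" sums them.
#' @return percentage.
#' @export
magnitudeError <- function(match, tHat, tGt, groundTruth,
                           aggregate = c("mean", "as_printed")) {
  aggregate <- match.arg(aggregate)
  .check_match(match)
  magHat <- fieldMagnitude(tHat)
  magGt <- fieldMagnitude(tGt)
  per <- vapply(seq_len(nrow(match$pairs)), function(i) {
    p <- groundTruth@pixels[[match$pairs$gt[i]]]
    100 * sum(abs(magHat[p] - magGt[p])) / sum(magGt[p])
  }, numeric(1))
  if (aggregate == "mean") mean(per) else sum(per)
}

#' Angular error of the recovered tractions
#'
#' Per matched footprint, the mean absolute angle between recovered and
#' ground-truth traction vectors over the associated ground-truth
#' footprint pixels, weighted by the recovered magnitude, normalized by
#' the maximum error (180 degrees) and expressed in percent. Pixels where
#' either field vanishes are excluded (the angle is undefined there).
#'
#' @inheritParams magnitudeError
#' @return percentage in [0, 100].
#' @export
angleError <- function(match, tHat, tGt, groundTruth,
                       aggregate = c("mean", "as_printed")) {
  aggregate <- match.arg(aggregate)
  .check_match(match)
  magHat <- fieldMagnitude(tHat)
  magGt <- fieldMagnitude(tGt)
  per <- vapply(seq_len(nrow(match$pairs)), function(i) {
    p <- groundTruth@pixels[[match$pairs$gt[i]]]
    p <- p[magHat[p] > 0 & magGt[p] > 0]
    if (!length(p)) return(NA_real_)
    dot <- tHat@x[p] * tGt@x[p] + tHat@y[p] * tGt@y[p]
    cosang <- pmin(pmax(dot / (magHat[p] * magGt[p]), -1), 1)
    ang <- acos(cosang) * 180 / pi
    w <- magHat[p] / sum(magHat[p])
    100 * sum(w * abs(ang)) / 180
  }, numeric(1))
  per <- per[!is.na(per)]
  if (!length(per)) stop("no matched footprint had nonzero tractions")
  if (aggregate == "mean") mean(per) else sum(per)
}

#' Error in recovered stress-footprint area
#'
#' Per matched footprint, 100 * |A_hat - A_gt| / A_gt, aggregated over
#' footprints.
#'
#' @inheritParams magnitudeError
#' @param recovered the recovered [FootprintSet-class].
#' @return percentage.
#' @export
areaError <- function(match, recovered, groundTruth,
                      aggregate = c("mean", "as_printed")) {
  aggregate <- match.arg(aggregate)
  .check_match(match)
  aHat <- recovered@table$area_um2[match$pairs$recovered]
  aGt <- groundTruth@table$area_um2[match$pairs$gt]
  per <- 100 * abs(aHat - aGt) / aGt
  if (aggregate == "mean") mean(per) else sum(per)
}

#' Loss ratio of stress footprints
#'
#' Percentage of simulated stress footprints that the recovery failed to
#' find: 100 * (n_gt - n_recovered) / n_gt.
#'
#' @param nGt number of ground-truth footprints (>= 1).
#' @param nRecovered number of distinct ground-truth footprints recovered
#'   (<= nGt).
#' @return percentage in [0, 100].
#' @examples
#' lossRatio(10, 7)  # 30
#' @export
lossRatio <- function(nGt, nRecovered) {
  stopifnot(nGt >= 1, nRecovered >= 0, nRecovered <= nGt)
  100 * (nGt - nRecovered) / nGt
}

#' Smallest detectable stress footprint
#'
#' The smallest product of ground-truth footprint area (um^2) and peak
#' traction magnitude (kPa) among the recovered footprints, in nN
#' (1 kPa * um^2 = 1 nN). Reflects the joint size/magnitude detection
#' limit of a scheme.
#'
#' @param areaGt_um2 ground-truth areas of the recovered footprints, um^2.
#' @param peak_kPa peak traction magnitudes of those footprints, kPa.
#' @return smallest area-force product in nN.
#' @examples
#' smallestDetectable(0.25, 0.68)  # 0.17 nN
#' @export
smallestDetectable <- function(areaGt_um2, peak_kPa) {
  stopifnot(length(areaGt_um2) >= 1,
            length(areaGt_um2) == length(peak_kPa))
  min(areaGt_um2 * peak_kPa)
}

#' Net traction balance of a field
#'
#' Componentwise sums of the traction field over all pixels, and their
#' largest absolute value as a percentage of the maximum traction
#' magnitude. For a cell in mechanical equilibrium the net traction is
#' zero; the inverse solvers do not impose this, so a small residual sum
#' is a useful consistency check.
#'
#' @param t a traction [VectorField2D-class].
#' @return named list: `sum_x`, `sum_y` (Pa) and `pct_of_max` (defined as
#'   0 for an all-zero field).
#' @export
netTractionBalance <- function(t) {
  validObject(t)
  sx <- sum(t@x); sy <- sum(t@y)
  mx <- max(fieldMagnitude(t))
  pct <- if (mx == 0) 0 else 100 * max(abs(sx), abs(sy)) / mx
  list(sum_x = sx, sum_y = sy, pct_of_max = pct)
}

#' Full metrics report for one recovery
#'
#' Computes every error metric for a recovered traction field against its
#' ground truth: footprints are extracted from both fields with the
#' 2-level isodata mask, matched by maximal overlap, and the five metrics
#' plus the net traction balance are assembled into a one-row data.frame.
#'
#' @param tHat,tGt recovered and ground-truth traction
#'   [VectorField2D-class] fields.
#' @param substrate a [Substrate-class].
#' @return one-row data.frame with columns e_m, e_a, e_A, LFA, SFA,
#'   net_sum_x, net_sum_y, net_pct, n_gt, n_recovered, n_spurious.
#'   Metrics that need matched footprints are NA when nothing matched.
#' @export
metricsReport <- function(tHat, tGt, substrate) {
  fpHat <- extractFootprints(footprintMask(tHat, "metrics_2level"),
                             tHat, substrate)
  fpGt <- extractFootprints(footprintMask(tGt, "metrics_2level"),
                            tGt, substrate)
  m <- matchFootprints(fpHat, fpGt)
  nGt <- nrow(fpGt@table)
  bal <- netTractionBalance(tHat)
  matched <- nrow(m$pairs) > 0
  sfa <- if (matched)
    smallestDetectable(fpGt@table$area_um2[m$pairs$gt],
                       fpHat@table$peak_Pa[m$pairs$recovered] / 1000)
  else NA_real_
  data.frame(
    e_m = if (matched) magnitudeError(m, tHat, tGt, fpGt) else NA_real_,
    e_a = if (matched) angleError(m, tHat, tGt, fpGt) else NA_real_,
    e_A = if (matched) areaError(m, fpHat, fpGt) else NA_real_,
    LFA = if (nGt >= 1) lossRatio(nGt, m$nMatchedGT) else NA_real_,
    SFA = sfa,
    net_sum_x = bal$sum_x, net_sum_y = bal$sum_y, net_pct = bal$pct_of_max,
    n_gt = nGt, n_recovered = m$nMatchedGT,
    n_spurious = length(m$spurious))
}
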