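#' @import methods
NULL

#' Elastic substrate parameters
#'
#' Describes the hydrogel substrate of a 2D TFM experiment as a homogeneous,
#' isotropic, semi-infinite linear-elastic half-space, together with the
#' regular pixel grid on which displacements and tractions are sampled.
#'
#' @slot youngModulus Young's modulus of the gel in Pa (> 0).
#' @slot poissonRatio Poisson ratio, dimensionless, in [0, 0.5].
#' @slot pixelSpacing grid spacing in micrometres (> 0).
#'
#' @examples
#' Substrate(youngModulus = 5000, poissonRatio = 0.45, pixelSpacing = 0.32)
#' @export
setClass("Substrate",
  representation(
    youngModulus = "numeric",
    poissonRatio = "numeric",
    pixelSpacing = "numeric"
  )
)

setValidity("Substrate", function(object) {
  msg <- character()
  if (length(object@youngModulus) != 1 || !is.finite(object@youngModulus) ||
      object@youngModulus <= 0)
    msg <- c(msg, "youngModulus must be a single positive finite value (Pa)")
  if (length(object@poissonRatio) != 1 || !is.finite(object@poissonRatio) ||
      object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5]")
  if (length(object@pixelSpacing) != 1 || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive finite value (um)")
  if (length(msg)) msg else TRUE
})

#' @param youngModulus Young's modulus in Pa.
#' @param poissonRatio Poisson ratio in [0, 0.5].
#' @param pixelSpacing pixel spacing in micrometres.
#' @rdname Substrate-class
#' @export
Substrate <- function(youngModulus = 5000, poissonRatio = 0.45,
                      pixelSpacing = 0.32) {
  new("Substrate", youngModulus = as.numeric(youngModulus),
      poissonRatio = as.numeric(poissonRatio),
      pixelSpacing = as.numeric(pixelSpacing))
}

setMethod("show", "Substrate", function(object) {
  cat("Substrate: E =", object@youngModulus, "Pa, nu =",
      object@poissonRatio, ", h =", object@pixelSpacing, "um\n")
})

#' Two-component vector field on a regular grid
#'
#' Container for a planar vector field sampled on a regular pixel grid:
#' either a displacement field (micrometres) or a traction field (Pa).
#' Components are stored as matrices indexed [row, col] with 0-based pixel
#' coordinates mapping to physical positions index * spacing.
#'
#' @slot x matrix of x-components.
#' @slot y matrix of y-components, same dimensions as `x`.
#' @slot units either "um" (displacements) or "Pa" (tractions).
#' @slot spacing pixel spacing in micrometres.
#' @export
setClass("VectorField2D",
  representation(
    x = "matrix",
    y = "matrix",
    units = "character",
    spacing = "numeric"
  )
)

setValidity("VectorField2D", function(object) {
  msg <- character()
  if (!identical(dim(object@x), dim(object@y)))
    msg <- c(msg, "x and y components must have identical dimensions")
  if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
    msg <- c(msg, "all field values must be finite")
  if (!object@units %in% c("um", "Pa"))
    msg <- c(msg, "units must be 'um' or 'Pa'")
  if (length(object@spacing) != 1 || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' @param x,y component matrices (identical dimensions).
#' @param units "um" or "Pa".
#' @param spacing pixel spacing in micrometres.
#' @rdname VectorField2D-class
#' @export
VectorField2D <- function(x, y, units, spacing) {
  new("VectorField2D", x = as.matrix(x), y = as.matrix(y),
      units = units, spacing = as.numeric(spacing))
}

#' @rdname VectorField2D-class
#' @export
DisplacementField <- function(x, y, spacing) VectorField2D(x, y, "um", spacing)

#' @rdname VectorField2D-class
#' @export
TractionField <- function(x, y, spacing) VectorField2D(x, y, "Pa", spacing)

setMethod("show", "VectorField2D", function(object) {
  d <- dim(object@x)
  cat(sprintf("VectorField2D: %d x %d grid, units %s, spacing %g um\n",
              d[1], d[2], object@units, object@spacing))
  m <- fieldMagnitude(object)
  cat(sprintf("  |v| range: [%g, %g] %s\n", min(m), max(m), object@units))
})

#' Discrete Green operator mapping tractions to displacements
#'
#' Dense 2N x 2M stiffness matrix K with block structure
#' [Gxx Gxy; Gyx Gyy], where N observation points index the displacement
#' vector [u_x; u_y] and M source points the traction vector [t_x; t_y].
#' Entries are in um/Pa.
#'
#' @slot matrix the dense 2N x 2M matrix.
#' @slot obsPoints N x 2 matrix of observation pixel coordinates (row, col).
#' @slot srcPoints M x 2 matrix of source pixel coordinates (row, col).
#' @slot substrate the [Substrate-class] used for assembly.
#' @export
setClass("StiffnessMatrix",
  representation(
    matrix = "matrix",
    obsPoints = "matrix",
    srcPoints = "matrix",
    substrate = "Substrate"
  )
)

setValidity("StiffnessMatrix", function(object) {
  N <- nrow(object@obsPoints); M <- nrow(object@srcPoints)
  msg <- character()
  if (!identical(dim(object@matrix), c(2L * N, 2L * M)))
    msg <- c(msg, "matrix must be 2N x 2M for N obs and M src points")
  if (!all(is.finite(object@matrix)))
    msg <- c(msg, "all stiffness entries must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StiffnessMatrix", function(object) {
  cat(sprintf("StiffnessMatrix: %d x %d (N = %d obs, M = %d src), um/Pa\n",
              nrow(object@matrix), ncol(object@matrix),
              nrow(object@obsPoints), nrow(object@srcPoints)))
})

#' Regularization settings for the inverse solvers
#'
#' @slot scheme one of "l2_fourier", "l2_spatial", "l1", "full_l1".
#' @slot lambda regularization parameter (>= 0), in the um/Pa unit system.
#' @slot irlsTol IRLS convergence threshold on the max absolute traction
#'   change between iterations, in Pa.
#' @slot irlsMaxIter maximum IRLS iterations.
#' @slot weightEps floor applied inside IRLS weights (Pa for the penalty
#'   weights, um for the data-fidelity weights) to bound conditioning.
#' @slot tractionUnit unit system in which the cost functional is posed:
#'   "Pa" applies lambda to the operator exactly as given (pure linear
#'   algebra); "kPa" rescales the stiffness operator to um/kPa inside the
#'   solver, so that for soft substrates (E of a few kPa, tractions of
#'   order 1 kPa) the data-fidelity and penalty terms are commensurate and
#'   lambda values in [0, 1] span the useful regularization range for all
#'   schemes. Recovered tractions are always returned in Pa.
#' @slot normalizeLambda if TRUE, lambda is additionally multiplied by
#'   max diag(K'K) before use.
#' @export
setClass("RegularizationConfig",
  representation(
    scheme = "character",
    lambda = "numeric",
    irlsTol = "numeric",
    irlsMaxIter = "integer",
    weightEps = "numeric",
    tractionUnit = "character",
    normalizeLambda = "logical"
  )
)

setValidity("RegularizationConfig", function(object) {
  msg <- character()
  if (!object@scheme %in% c("l2_fourier", "l2_spatial", "l1", "full_l1"))
    msg <- c(msg, "unknown scheme")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@irlsTol <= 0) msg <- c(msg, "irlsTol must be > 0")
  if (object@irlsMaxIter < 1L) msg <- c(msg, "irlsMaxIter must be >= 1")
  if (object@weightEps <= 0) msg <- c(msg, "weightEps must be > 0")
  if (!object@tractionUnit %in% c("Pa", "kPa"))
    msg <- c(msg, "tractionUnit must be 'Pa' or 'kPa'")
  if (length(msg)) msg else TRUE
})

#' @param scheme regularization scheme.
#' @param lambda regularization parameter.
#' @param irlsTol,irlsMaxIter,weightEps IRLS controls, see slots.
#' @param tractionUnit,normalizeLambda see slots.
#' @rdname RegularizationConfig-class
#' @export
regConfig <- function(scheme = c("l2_spatial", "l2_fourier", "l1", "full_l1"),
                      lambda = 0.1, irlsTol = 1e-6, irlsMaxIter = 100L,
                      weightEps = 1e-8, tractionUnit = c("Pa", "kPa"),
                      normalizeLambda = FALSE) {
  scheme <- match.arg(scheme)
  tractionUnit <- match.arg(tractionUnit)
  new("RegularizationConfig", scheme = scheme, lambda = as.numeric(lambda),
      irlsTol = as.numeric(irlsTol), irlsMaxIter = as.integer(irlsMaxIter),
      weightEps = as.numeric(weightEps), tractionUnit = tractionUnit,
      normalizeLambda = isTRUE(normalizeLambda))
}

setMethod("show", "RegularizationConfig", function(object) {
  cat(sprintf("RegularizationConfig: %s, lambda = %g\n",
              object@scheme, object@lambda))
})

#' Result of a regularized inverse solve
#'
#' @slot tractions recovered tractions: a [VectorField2D-class] for
#'   field-level solvers, or a bare numeric vector [t_x; t_y] for the
#'   matrix-level solvers.
#' @slot iterations number of linear solves performed (1 for closed-form
#'   schemes).
#' @slot converged TRUE unless an IRLS scheme hit `irlsMaxIter` first.
#' @slot residualL2,residualL1 data-fidelity residual norms ||Kt - u|| (um).
#' @slot penaltyL2,penaltyL1 penalty norms of the solution (Pa).
#' @slot objectiveTrace merit value after each linear solve (length =
#'   iterations): the cost functional for the closed-form schemes, and
#'   for the IRLS schemes the majorize-minimize surrogate the iteration
#'   provably decreases (Huber-smoothed norms from the eps-floored
#'   weights, factor 2 on each reweighted term).
#' @export
setClass("SolveResult",
  representation(
    tractions = "ANY",
    iterations = "integer",
    converged = "logical",
    residualL2 = "numeric",
    residualL1 = "numeric",
    penaltyL2 = "numeric",
    penaltyL1 = "numeric",
    objectiveTrace = "numeric"
  )
)

setMethod("show", "SolveResult", function(object) {
  cat(sprintf(
    "SolveResult: %d iteration(s), converged = %s\n  ||Kt-u||_2 = %g um, ||t||_1 = %g Pa\n",
    object@iterations, object@converged, object@residualL2, object@penaltyL1))
})

#' Labeled disjoint regions of a field
#'
#' Output of the displacement-magnitude segmentation that drives the
#' stiffness-matrix reduction. Labels are contiguous 1..regionCount over an
#' integer label image (0 = background); regions are 8-connected components.
#'
#' @slot labelImage integer matrix of region labels.
#' @slot regionCount number of regions.
#' @slot pixels list of integer vectors; linear (column-major) pixel indices
#'   per region.
#' @export
setClass("RegionSet",
  representation(
    labelImage = "matrix",
    regionCount = "integer",
    pixels = "list"
  )
)

setValidity("RegionSet", function(object) {
  msg <- character()
  labs <- sort(unique(as.integer(object@labelImage)))
  labs <- labs[labs > 0L]
  if (length(labs) != object@regionCount ||
      (length(labs) && !identical(labs, seq_len(object@regionCount))))
    msg <- c(msg, "labels must be contiguous 1..regionCount")
  if (length(object@pixels) != object@regionCount)
    msg <- c(msg, "pixels list length must equal regionCount")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegionSet", function(object) {
  sizes <- lengths(object@pixels)
  cat(sprintf("RegionSet: %d region(s), sizes [%s] px\n", object@regionCount,
              paste(sizes, collapse = ", ")))
})

#' Segmented stress footprints of a traction field
#'
#' A set of connected high-traction regions (stress footprints: clusters of
#' focal adhesions) extracted from a traction magnitude mask, with the
#' per-footprint quantities used by the error metrics.
#'
#' @slot table data.frame with columns label, n_pixels, area_um2, peak_Pa,
#'   centroid_row, centroid_col.
#' @slot pixels list of linear pixel index vectors, one per footprint.
#' @slot fieldDim dimensions of the source grid.
#' @export
setClass("FootprintSet",
  representation(
    table = "data.frame",
    pixels = "list",
    fieldDim = "integer"
  )
)

setMethod("show", "FootprintSet", function(object) {
  cat(sprintf("FootprintSet: %d footprint(s) on a %d x %d grid\n",
              nrow(object@table), object@fieldDim[1], object@fieldDim[2]))
  if (nrow(object@table))
    print(utils::head(object@table, 10))
})

#' Specification of a synthetic TFM benchmark case
#'
#' Defines the statistical conditions under which synthetic cases are drawn:
#' sparse stress footprints with random position, direction, peak and area,
#' on a hydrogel with given elasticity, imaged at a given pixel size.
#'
#' @slot gridShape c(rows, cols) of the simulated field.
#' @slot substrate a [Substrate-class].
#' @slot footprintRange integer range c(min, max) of footprints per case.
#' @slot peakRange peak traction range in kPa.
#' @slot areaRange footprint area range in um^2 (log-uniform sampling).
#' @slot footprintShape "gaussian" or "disk" blob profile.
#' @slot directionMode "paired" (default): footprints come in contractile
#'   pairs -- two identical blobs pulling toward each other along a random
#'   axis, like focal-adhesion clusters coupled by a stress fiber -- so
#'   every pair balances exactly and the displacement halo decays as a
#'   force dipole; "random": independent uniform directions with a global
#'   net-traction correction.
#' @slot cellFraction footprint centres are confined to a concentric disk
#'   of diameter `cellFraction * min(gridShape)` pixels, emulating a cell
#'   centred in the field of view; together with the zero net traction
#'   this gives the dipole-like far-field displacement decay of real
#'   cells.
#' @slot noiseSigma displacement noise s.d. in um; NA means 10% of the
#'   median ideal displacement magnitude, computed per case.
#' @slot nRealizations noise realizations per case.
#' @export
setClass("SimulationSpec",
  representation(
    gridShape = "integer",
    substrate = "Substrate",
    footprintRange = "integer",
    peakRange = "numeric",
    areaRange = "numeric",
    footprintShape = "character",
    directionMode = "character",
    cellFraction = "numeric",
    noiseSigma = "numeric",
    nRealizations = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 2 || any(object@gridShape < 8))
    msg <- c(msg, "gridShape must be two integers >= 8")
  if (object@footprintRange[1] < 1 ||
      object@footprintRange[2] < object@footprintRange[1])
    msg <- c(msg, "footprintRange must be an increasing positive range")
  if (any(object@peakRange <= 0) || any(object@areaRange <= 0))
    msg <- c(msg, "peak and area ranges must be positive")
  if (!object@footprintShape %in% c("gaussian", "disk"))
    msg <- c(msg, "footprintShape must be 'gaussian' or 'disk'")
  if (!object@directionMode %in% c("paired", "random"))
    msg <- c(msg, "directionMode must be 'paired' or 'random'")
  if (object@cellFraction <= 0 || object@cellFraction > 1)
    msg <- c(msg, "cellFraction must be in (0, 1]")
  if (!is.na(object@noiseSigma) && object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0 (or NA for the 10% rule)")
  if (length(msg)) msg else TRUE
})

#' @param gridShape,substrate,footprintRange,peakRange,areaRange see slots.
#' @param footprintShape,noiseSigma,nRealizations see slots.
#' @rdname SimulationSpec-class
#' @export
simulationSpec <- function(gridShape = c(256L, 256L),
                           substrate = Substrate(5000, 0.45, 0.32),
                           footprintRange = c(10L, 120L),
                           peakRange = c(0.6, 4),
                           areaRange = c(0.25, 20),
                           footprintShape = "gaussian",
                           directionMode = "paired",
                           cellFraction = 0.8,
                           noiseSigma = NA_real_,
                           nRealizations = 10L) {
  new("SimulationSpec", gridShape = as.integer(gridShape),
      substrate = substrate, footprintRange = as.integer(footprintRange),
      peakRange = as.numeric(peakRange), areaRange = as.numeric(areaRange),
      footprintShape = footprintShape, directionMode = directionMode,
      cellFraction = as.numeric(cellFraction),
      noiseSigma = as.numeric(noiseSigma),
      nRealizations = as.integer(nRealizations))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d x %d grid, %d-%d footprints, peaks %g-%g kPa, areas %g-%g um^2\n",
    object@gridShape[1], object@gridShape[2],
    object@footprintRange[1], object@footprintRange[2],
    object@peakRange[1], object@peakRange[2],
    object@areaRange[1], object@areaRange[2]))
})
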