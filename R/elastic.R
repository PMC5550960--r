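## Discrete Boussinesq forward model for 2D TFM.
##
## The substrate is a homogeneous, isotropic, semi-infinite elastic
## half-space; cells exert purely tangential (in-plane) tractions on its
## surface. The displacement response to a tangential point force is the
## Boussinesq surface Green function
##
##   g_ij(x) = (1+nu) / (pi E r^3) * [ (1-nu) r^2 delta_ij + nu x_i x_j ]
##
## with r = ||x||. Discretizing tractions as piecewise-constant on square
## pixels of side h gives stiffness entries g_ji(x_n - x'_m) * h^2; the
## singular self-term (zero offset) is the kernel integrated analytically
## over the source pixel, which is finite.

# integral of 1/r over a square of side h centred at the origin
.int_inv_r_square <- function(h) 4 * h * log(1 + sqrt(2))

# analytic self-term: integral of g_xx (= g_yy) over the centred source
# pixel; the off-diagonal integral vanishes by symmetry.
.self_term_diag <- function(substrate) {
  E <- substrate@youngModulus
  nu <- substrate@poissonRatio
  h <- substrate@pixelSpacing
  I1 <- .int_inv_r_square(h)
  # int (1-nu)/r + nu x^2/r^3 dA = (1-nu) I1 + nu I1/2
  (1 + nu) / (pi * E) * I1 * (1 - nu / 2)
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# raw kernel tensor components at physical offsets (vectorized);
# offsets in um, result in 1/(Pa um)
.kernel_raw <- function(dx, dy, substrate) {
  E <- substrate@youngModulus
  nu <- substrate@poissonRatio
  C <- (1 + nu) / (pi * E)
  r2 <- dx^2 + dy^2
  r <- sqrt(r2)
  r3 <- r2 * r
  gxx <- C * ((1 - nu) / r + nu * dx^2 / r3)
  gyy <- C * ((1 - nu) / r + nu * dy^2 / r3)
  gxy <- C * nu * dx * dy / r3
  list(xx = gxx, xy = gxy, yy = gyy)
}

#' Boussinesq surface Green function of the substrate
#'
#' Evaluates the 2x2 tangential Boussinesq tensor g(x - x') of a
#' semi-infinite, homogeneous, isotropic elastic half-space at a given
#' in-plane offset. At zero offset the singularity is resolved by
#' integrating the kernel analytically over the square source pixel (side
#' `pixelSpacing`) and dividing by the pixel area, so the returned tensor
#' is always finite and in the same per-unit-area units.
#'
#' @param offset numeric length-2 in-plane offset (x, y) in micrometres.
#' @param substrate a [Substrate-class].
#' @return 2x2 symmetric matrix in um/(Pa um^2); multiply by the pixel area
#'   to obtain a stiffness-matrix entry in um/Pa.
#' @examples
#' sub <- Substrate(5000, 0.45, 0.32)
#' boussinesqKernel(c(2, 0), sub)
#' @export
boussinesqKernel <- function(offset, substrate) {
  stopifnot(length(offset) == 2, all(is.finite(offset)))
  validObject(substrate)
  h <- substrate@pixelSpacing
  if (all(offset == 0)) {
    d <- .self_term_diag(substrate) / h^2
    return(matrix(c(d, 0, 0, d), 2, 2))
  }
  g <- .kernel_raw(offset[1], offset[2], substrate)
  matrix(c(g$xx, g$xy, g$xy, g$yy), 2, 2)
}

# discrete kernel entries (um/Pa) for integer pixel offsets, vectorized.
# quadrature "center": g at the offset times h^2; "full": tensor-product
# Gauss-Legendre integration of g over the source pixel. The zero offset
# always uses the analytic pixel integral.
.kernel_discrete <- function(drow, dcol, substrate,
                             quadrature = c("center", "full"),
                             quad_order = 12L) {
  quadrature <- match.arg(quadrature)
  h <- substrate@pixelSpacing
  dx <- dcol * h
  dy <- drow * h
  zero <- drow == 0L & dcol == 0L
  if (quadrature == "center") {
    g <- .kernel_raw(dx, dy, substrate)
    kxx <- g$xx * h^2; kxy <- g$xy * h^2; kyy <- g$yy * h^2
  } else {
    gl <- .gauss_legendre(quad_order)
    xs <- gl$x * h / 2
    ws <- gl$w * h / 2
    kxx <- kxy <- kyy <- numeric(length(dx))
    for (i in seq_along(xs)) {
      for (j in seq_along(xs)) {
        g <- .kernel_raw(dx - xs[i], dy - xs[j], substrate)
        wij <- ws[i] * ws[j]
        kxx <- kxx + wij * g$xx
        kxy <- kxy + wij * g$xy
        kyy <- kyy + wij * g$yy
      }
    }
  }
  if (any(zero)) {
    s <- .self_term_diag(substrate)
    kxx[zero] <- s; kyy[zero] <- s; kxy[zero] <- 0
  }
  list(xx = kxx, xy = kxy, yy = kyy)
}

#' Assemble the dense stiffness matrix
#'
#' Builds the 2N x 2M discrete Green operator K = [Gxx Gxy; Gyx Gyy]
#' mapping the traction vector [t_x; t_y] at M source pixels to the
#' displacement vector [u_x; u_y] at N observation pixels, on the regular
#' grid of the substrate.
#'
#' @param obsPoints N x 2 matrix of observation pixel indices (row, col),
#'   1-based, integer-valued.
#' @param srcPoints M x 2 matrix of source pixel indices; defaults to
#'   `obsPoints`.
#' @param substrate a [Substrate-class].
#' @param quadrature "center" (default): off-centre entries are the kernel
#'   at the offset times the pixel area; "full": Gauss-Legendre integration
#'   of the kernel over each source pixel. The self-term is always the
#'   analytic pixel integral.
#' @return a [StiffnessMatrix-class]; entries in um/Pa.
#' @examples
#' sub <- Substrate(5000, 0.45, 0.32)
#' pts <- gridPoints(c(3, 3))
#' K <- assembleStiffness(pts, substrate = sub)
#' dim(stiffness(K))  # 18 x 18
#' @export
assembleStiffness <- function(obsPoints, srcPoints = obsPoints, substrate,
                              quadrature = c("center", "full")) {
  quadrature <- match.arg(quadrature)
  validObject(substrate)
  obsPoints <- as.matrix(obsPoints)
  srcPoints <- as.matrix(srcPoints)
  if (nrow(obsPoints) == 0 || nrow(srcPoints) == 0)
    stop("point lists must be nonempty")
  if (ncol(obsPoints) != 2 || ncol(srcPoints) != 2)
    stop("points must be given as (row, col) pairs")
  if (any(obsPoints != round(obsPoints)) || any(srcPoints != round(srcPoints)))
    stop("points must lie on the common pixel grid of the substrate ",
         "(integer indices at spacing ", substrate@pixelSpacing, " um)")
  N <- nrow(obsPoints); M <- nrow(srcPoints)
  drow <- outer(obsPoints[, 1], srcPoints[, 1], "-")
  dcol <- outer(obsPoints[, 2], srcPoints[, 2], "-")
  k <- .kernel_discrete(drow, dcol, substrate, quadrature)
  K <- matrix(0, 2 * N, 2 * M)
  K[seq_len(N), seq_len(M)] <- k$xx
  K[seq_len(N), M + seq_len(M)] <- k$xy
  K[N + seq_len(N), seq_len(M)] <- k$xy
  K[N + seq_len(N), M + seq_len(M)] <- k$yy
  new("StiffnessMatrix", matrix = K,
      obsPoints = obsPoints, srcPoints = srcPoints, substrate = substrate)
}

#' Enumerate all pixels of a grid
#'
#' @param dims c(rows, cols).
#' @return (rows*cols) x 2 matrix of (row, col) indices in column-major
#'   order, matching R's linear matrix indexing.
#' @export
gridPoints <- function(dims) {
  cbind(row = rep(seq_len(dims[1]), times = dims[2]),
        col = rep(seq_len(dims[2]), each = dims[1]))
}

# 2D FFT-based aperiodic convolution machinery -------------------------------

# kernel component matrices laid out for circular convolution on an L1 x L2
# padded grid, offsets -(P-1)..(P-1) wrapped to the FFT origin
.kernel_fft_grids <- function(dims, L, substrate, quadrature = "center") {
  off1 <- c(0:(dims[1] - 1), -( (L[1] - dims[1]):1 ))
  off2 <- c(0:(dims[2] - 1), -( (L[2] - dims[2]):1 ))
  # offsets beyond (P-1) in the wrapped tail never touch the valid output
  # region, but evaluating them is harmless (kernel decays as 1/r)
  drow <- matrix(off1, L[1], L[2])
  dcol <- matrix(off2, L[1], L[2], byrow = TRUE)
  .kernel_discrete(drow, dcol, substrate, quadrature)
}

.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Forward model: displacements generated by a traction field
#'
#' Computes u = K t for a full rectangular traction field by aperiodic
#' (zero-padded) FFT convolution with the discrete Boussinesq kernel. This
#' is algebraically identical to assembling the dense stiffness matrix over
#' the full grid and multiplying, but runs in O(P log P).
#'
#' @param t a traction [VectorField2D-class] in Pa.
#' @param substrate a [Substrate-class].
#' @param quadrature passed to the discrete kernel, see
#'   [assembleStiffness()].
#' @return a displacement [VectorField2D-class] in um on the same grid.
#' @examples
#' sub <- Substrate(5000, 0.45, 0.32)
#' tx <- matrix(0, 32, 32); tx[16, 16] <- 1000
#' u <- forwardDisplacements(TractionField(tx, 0 * tx, 0.32), sub)
#' @export
forwardDisplacements <- function(t, substrate,
                                 quadrature = c("center", "full")) {
  quadrature <- match.arg(quadrature)
  validObject(t); validObject(substrate)
  if (t@units != "Pa") stop("forwardDisplacements expects tractions in Pa")
  if (abs(t@spacing - substrate@pixelSpacing) > 1e-12)
    stop("traction field spacing does not match the substrate grid")
  dims <- dim(t@x)
  L <- c(stats::nextn(2 * dims[1], c(2, 3)),
         stats::nextn(2 * dims[2], c(2, 3)))
  k <- .kernel_fft_grids(dims, L, substrate, quadrature)
  pad <- function(m) { p <- matrix(0, L[1], L[2]); p[seq_len(dims[1]), seq_len(dims[2])] <- m; p }
  Tx <- .fft2(pad(t@x)); Ty <- .fft2(pad(t@y))
  Kxx <- .fft2(k$xx); Kxy <- .fft2(k$xy); Kyy <- .fft2(k$yy)
  ux <- Re(.ifft2(Kxx * Tx + Kxy * Ty))[seq_len(dims[1]), seq_len(dims[2])]
  uy <- Re(.ifft2(Kxy * Tx + Kyy * Ty))[seq_len(dims[1]), seq_len(dims[2])]
  DisplacementField(ux, uy, substrate@pixelSpacing)
}
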