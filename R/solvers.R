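## Regularized inverse solvers.
##
## All four schemes minimize a cost functional of the form
##
##   t_hat = argmin_t  ||K t - u||_q  +  lambda ||t||_p
##
## with (q, p) = (2, 2) for Tikhonov/L2 (Fourier or spatial), (2, 1) for L1
## and (1, 1) for full-L1. The L2 cases use the classical closed-form ridge
## solutions, i.e. the squared-norm variants of the functional; the L1
## norms are handled by iteratively reweighted least squares (IRLS), which
## replaces each L1 norm by a weighted L2 norm re-derived from the previous
## iterate. lambda is an absolute value in the um/Pa unit system of the
## stiffness matrix (set `normalizeLambda` in the config to scale it by
## max diag(K'K) instead).

.as_kmat <- function(K) {
  if (is(K, "StiffnessMatrix")) K@matrix else as.matrix(K)
}

# operator scale of the solving unit system: in "kPa" mode the stiffness
# operator is rescaled to um/kPa and tractions are solved in kPa
.unit_scale <- function(cfg) if (cfg@tractionUnit == "kPa") 1000 else 1

.effective_lambda <- function(K, cfg) {
  lam <- cfg@lambda
  if (cfg@normalizeLambda)
    lam <- lam * max(colSums(K^2)) * .unit_scale(cfg)^2
  lam
}

# SPD solve via Cholesky with a clear error for the singular case
.spd_solve <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e)
    stop("normal equations are singular (rank-deficient K with lambda = 0?)",
         call. = FALSE))
  if (min(diag(R)) < 1e-7 * max(diag(R)))
    stop("normal equations are singular (rank-deficient K with lambda = 0?)",
         call. = FALSE)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

# Huber-smoothed absolute value matching the eps-floored IRLS weights
.huber_eps <- function(x, eps) {
  a <- abs(x)
  ifelse(a >= eps, a, x^2 / (2 * eps) + eps / 2)
}

# The merit function each IRLS iteration provably decreases
# (majorize-minimize surrogate of the scheme's cost functional; the
# eps-floored weights smooth the L1 norms into Huber form, and the
# quadratic majorization carries a factor 2 on each reweighted term).
.irls_merit <- function(t, r, lam, eps, reweightData) {
  if (reweightData)
    2 * sum(.huber_eps(r, eps)) + 2 * lam * sum(.huber_eps(t, eps))
  else
    sum(r^2) + 2 * lam * sum(.huber_eps(t, eps))
}

#' Value of the regularization cost functional
#'
#' Evaluates the scheme's cost functional at a candidate traction vector:
#' squared L2 data fidelity and penalty for the L2 schemes, squared L2
#' fidelity with an L1 penalty for the L1 scheme, and L1 norms for both
#' terms under full-L1.
#'
#' @param t numeric traction vector (2M).
#' @param u numeric displacement vector (2N).
#' @param K stiffness matrix ([StiffnessMatrix-class] or plain matrix).
#' @param cfg a [RegularizationConfig-class] (scheme and lambda are used).
#' @return scalar cost.
#' @export
costFunctional <- function(t, u, K, cfg) {
  K <- .as_kmat(K)
  r <- as.vector(K %*% t - u)
  lam <- .effective_lambda(K, cfg)
  ts <- t / .unit_scale(cfg)  # penalty posed in the solving units
  switch(cfg@scheme,
    l2_fourier = ,
    l2_spatial = sum(r^2) + lam * sum(ts^2),
    l1         = sum(r^2) + lam * sum(abs(ts)),
    full_l1    = sum(abs(r)) + lam * sum(abs(ts)))
}

.solve_result <- function(t, K, u, iterations, convergedFlag, trace) {
  r <- as.vector(K %*% t - u)
  new("SolveResult", tractions = as.vector(t),
      iterations = as.integer(iterations), converged = convergedFlag,
      residualL2 = sqrt(sum(r^2)), residualL1 = sum(abs(r)),
      penaltyL2 = sqrt(sum(t^2)), penaltyL1 = sum(abs(t)),
      objectiveTrace = trace)
}

#' Tikhonov (L2) regularization in the spatial domain
#'
#' Closed-form ridge solution of the normal equations,
#' t = (K'K + lambda I)^-1 K' u.
#'
#' @param K stiffness matrix ([StiffnessMatrix-class] or plain 2N x 2M
#'   matrix).
#' @param u numeric displacement vector of length 2N (um).
#' @param cfg a [RegularizationConfig-class] with scheme "l2_spatial".
#' @return a [SolveResult-class] whose `tractions` is a numeric 2M vector.
#' @export
solveL2Spatial <- function(K, u, cfg = regConfig("l2_spatial")) {
  K <- .as_kmat(K)
  u <- as.numeric(u)
  if (nrow(K) != length(u))
    stop("K and u are dimensionally inconsistent: 2N = ", nrow(K),
         " rows vs length(u) = ", length(u))
  s <- .unit_scale(cfg)
  Ks <- if (s != 1) K * s else K
  lam <- .effective_lambda(K, cfg)
  A <- crossprod(Ks)
  diag(A) <- diag(A) + lam
  t <- s * .spd_solve(A, crossprod(Ks, u))  # back to Pa
  .solve_result(t, K, u, 1L, TRUE, costFunctional(t, u, K, cfg))
}

#' IRLS penalty weights
#'
#' Diagonal of the weight matrix W that turns the L1 penalty into a
#' weighted L2 penalty: W_ii = 1 / max(|t_i|, eps). At t = t_prev the
#' weighted penalty t'Wt equals ||t_prev||_1 (up to the eps floor).
#'
#' @param tPrev numeric traction vector from the previous iterate.
#' @param eps positive floor preventing division by zero.
#' @return numeric vector of positive weights (the diagonal of W).
#' @examples
#' irlsPenaltyWeights(c(2, -4), 1e-8)  # 0.5, 0.25
#' @export
irlsPenaltyWeights <- function(tPrev, eps = 1e-8) {
  stopifnot(all(is.finite(tPrev)), eps > 0)
  1 / pmax(abs(tPrev), eps)
}

# shared IRLS driver; reweightData = TRUE gives the full-L1 iteration.
# Internally solves in the cfg's unit system (t in kPa when tractionUnit
# is "kPa"); results are reported in Pa.
.irls <- function(K, u, cfg, reweightData) {
  K <- .as_kmat(K)
  u <- as.numeric(u)
  if (nrow(K) != length(u))
    stop("K and u are dimensionally inconsistent")
  s <- .unit_scale(cfg)
  Ks <- if (s != 1) K * s else K
  lam <- .effective_lambda(K, cfg)
  eps <- cfg@weightEps
  KtK <- crossprod(Ks)
  Ktu <- crossprod(Ks, u)
  # warm start: the L2-spatial solution at the same lambda (this is also
  # the first IRLS iterate, with W = W_d = I)
  A <- KtK
  diag(A) <- diag(A) + lam
  t <- as.vector(.spd_solve(A, Ktu))
  r <- as.vector(Ks %*% t - u)
  trace <- .irls_merit(t, r, lam, eps, reweightData)
  convergedFlag <- FALSE
  iter <- 1L
  while (iter < cfg@irlsMaxIter) {
    iter <- iter + 1L
    w <- irlsPenaltyWeights(t, eps)
    if (reweightData) {
      wd <- 1 / pmax(abs(r), eps)
      Kw <- Ks * sqrt(wd)
      A <- crossprod(Kw)
      b <- crossprod(Ks, wd * u)
    } else {
      A <- KtK
      b <- Ktu
    }
    diag(A) <- diag(A) + lam * w
    tNew <- as.vector(.spd_solve(A, b))
    delta <- s * max(abs(tNew - t))  # convergence measured in Pa
    t <- tNew
    r <- as.vector(Ks %*% t - u)
    trace <- c(trace, .irls_merit(t, r, lam, eps, reweightData))
    if (delta < cfg@irlsTol) {
      convergedFlag <- TRUE
      break
    }
  }
  if (!convergedFlag)
    warning(sprintf(
      "IRLS (%s) did not reach tol %g within %d iterations",
      cfg@scheme, cfg@irlsTol, cfg@irlsMaxIter))
  .solve_result(s * t, K, u, iter, convergedFlag, trace)
}

#' L1-regularized solve by IRLS
#'
#' Minimizes the squared L2 data fidelity plus an L1 penalty on the
#' tractions by iterating t = (K'K + lambda W)^-1 K' u with
#' W_ii = 1 / max(|t_i|, eps) from the previous iterate, starting from the
#' L2-spatial solution at the same lambda. Convergence is declared when
#' the maximum absolute traction change drops below `irlsTol` (Pa);
#' otherwise the result is returned with `converged = FALSE` and a
#' warning.
#'
#' @inheritParams solveL2Spatial
#' @param cfg a [RegularizationConfig-class] with scheme "l1".
#' @return a [SolveResult-class].
#' @export
solveL1IRLS <- function(K, u, cfg = regConfig("l1")) {
  .irls(K, u, cfg, reweightData = FALSE)
}

#' Full-L1 regularized solve by IRLS
#'
#' Minimizes the L1 norms of both the data fidelity and the penalty term by
#' iterating t = (K' W_d K + lambda W)^-1 K' W_d u, where
#' W_d,ii = 1 / max(|(Kt - u)_i|, eps) reweights the residuals each
#' iteration and W is as in [solveL1IRLS()]. The L1 data fidelity is
#' robust to heavy-tailed noise and outliers in the displacement field.
#'
#' @inheritParams solveL2Spatial
#' @param cfg a [RegularizationConfig-class] with scheme "full_l1".
#' @return a [SolveResult-class].
#' @export
solveFullL1IRLS <- function(K, u, cfg = regConfig("full_l1")) {
  .irls(K, u, cfg, reweightData = TRUE)
}

#' Tikhonov (L2) regularization in the Fourier domain
#'
#' Solves the ridge problem per spatial frequency:
#' t = F^-1 { (A*A + lambda I)^-1 A* u~ }, where A(k) is the 2 x 2 transfer
#' matrix obtained by transforming the discrete spatial Boussinesq kernel.
#' The field is zero-padded to at least twice its size to suppress periodic
#' wrap-around, so the result closely matches the spatial-domain L2
#' solution at the same lambda when the tractions are interior to the
#' field.
#'
#' @param u a displacement [VectorField2D-class] (um) on the full
#'   rectangular grid (the Fourier path cannot use masked or irregular
#'   data).
#' @param substrate a [Substrate-class].
#' @param cfg a [RegularizationConfig-class] with scheme "l2_fourier".
#' @return a [SolveResult-class] whose `tractions` is a
#'   [VectorField2D-class] in Pa over the full grid.
#' @export
solveL2Fourier <- function(u, substrate, cfg = regConfig("l2_fourier")) {
  validObject(u); validObject(substrate)
  if (u@units != "um") stop("solveL2Fourier expects displacements in um")
  if (abs(u@spacing - substrate@pixelSpacing) > 1e-12)
    stop("displacement field spacing does not match the substrate grid")
  dims <- dim(u@x)
  L <- c(stats::nextn(2 * dims[1], c(2, 3)),
         stats::nextn(2 * dims[2], c(2, 3)))
  k <- .kernel_fft_grids(dims, L, substrate)
  s <- .unit_scale(cfg)
  Gxx <- .fft2(k$xx) * s; Gxy <- .fft2(k$xy) * s; Gyy <- .fft2(k$yy) * s
  pad <- function(m) { p <- matrix(0, L[1], L[2]); p[seq_len(dims[1]), seq_len(dims[2])] <- m; p }
  Ux <- .fft2(pad(u@x)); Uy <- .fft2(pad(u@y))
  lam <- cfg@lambda
  if (cfg@normalizeLambda) {
    # diagonal of the circulant K'K, identical for every column
    lam <- lam * mean(Mod(Gxx)^2 + Mod(Gxy)^2)
  }
  # per-frequency normal equations (A^H A + lambda I) t~ = A^H u~
  B11 <- Mod(Gxx)^2 + Mod(Gxy)^2 + lam
  B22 <- Mod(Gxy)^2 + Mod(Gyy)^2 + lam
  B12 <- Conj(Gxx) * Gxy + Conj(Gxy) * Gyy
  c1 <- Conj(Gxx) * Ux + Conj(Gxy) * Uy
  c2 <- Conj(Gxy) * Ux + Conj(Gyy) * Uy
  det <- B11 * B22 - B12 * Conj(B12)
  Tx <- (B22 * c1 - B12 * c2) / det
  Ty <- (B11 * c2 - Conj(B12) * c1) / det
  tx <- s * Re(.ifft2(Tx))[seq_len(dims[1]), seq_len(dims[2])]
  ty <- s * Re(.ifft2(Ty))[seq_len(dims[1]), seq_len(dims[2])]
  tf <- TractionField(tx, ty, substrate@pixelSpacing)
  uf <- forwardDisplacements(tf, substrate)
  r <- c(uf@x - u@x, uf@y - u@y)
  t <- c(tx, ty)
  new("SolveResult", tractions = tf, iterations = 1L, converged = TRUE,
      residualL2 = sqrt(sum(r^2)), residualL1 = sum(abs(r)),
      penaltyL2 = sqrt(sum(t^2)), penaltyL1 = sum(abs(t)),
      objectiveTrace = sum(r^2) + lam * sum((t / s)^2))
}

# dispatch a spatial-domain scheme on (K, u)
.solve_spatial <- function(K, u, cfg) {
  switch(cfg@scheme,
    l2_spatial = solveL2Spatial(K, u, cfg),
    l1         = solveL1IRLS(K, u, cfg),
    full_l1    = solveFullL1IRLS(K, u, cfg),
    stop("scheme '", cfg@scheme, "' is not a spatial-domain scheme"))
}

#' Exhaustive search over the regularization parameter
#'
#' Solves the inverse problem on a grid of lambda values (the default grid
#' is 0 to 1 in steps of 0.01) and selects the best one. With a ground
#' truth available the criterion is the least-squares error between
#' recovered and true tractions; otherwise it is the value of the scheme's
#' cost functional. Both criteria are returned for every lambda.
#'
#' @param K stiffness matrix.
#' @param u numeric displacement vector (2N).
#' @param scheme spatial-domain scheme name ("l2_spatial", "l1",
#'   "full_l1").
#' @param lamGrid nonempty vector of nonnegative lambda values.
#' @param groundTruth optional numeric traction vector (2M) to compare
#'   against.
#' @param ... further arguments passed to [regConfig()] (e.g.
#'   `irlsMaxIter`).
#' @return list with `lambda` (the selected value), `criterion`
#'   ("ground_truth" or "cost"), and `table`, a data.frame with columns
#'   lambda, gt_error, cost, converged.
#' @export
lambdaSearch <- function(K, u, scheme = "l2_spatial",
                         lamGrid = seq(0, 1, by = 0.01),
                         groundTruth = NULL, ...) {
  stopifnot(length(lamGrid) >= 1, all(lamGrid >= 0))
  K <- .as_kmat(K)
  rows <- lapply(lamGrid, function(lam) {
    cfg <- regConfig(scheme, lambda = lam, ...)
    res <- tryCatch(
      suppressWarnings(.solve_spatial(K, u, cfg)),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(lambda = lam, gt_error = NA_real_, cost = NA_real_,
                        converged = NA))
    t <- res@tractions
    gt <- if (is.null(groundTruth)) NA_real_ else
      sqrt(sum((t - groundTruth)^2))
    data.frame(lambda = lam, gt_error = gt,
               cost = costFunctional(t, u, K, cfg),
               converged = res@converged)
  })
  tab <- do.call(rbind, rows)
  crit <- if (is.null(groundTruth)) "cost" else "ground_truth"
  score <- if (crit == "cost") tab$cost else tab$gt_error
  if (all(!is.finite(score))) stop("no lambda in the grid produced a solution")
  best <- which.min(replace(score, !is.finite(score), Inf))
  list(lambda = tab$lambda[best], criterion = crit, table = tab)
}
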