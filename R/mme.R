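# Henderson's mixed-model equations: assembly, preconditioned conjugate
# gradient solver, and the ssGBLUP solution report.

# Assemble W = [X Z ... Z] and C = W'W + blockdiag(0, lambda_k * Hinv_k).
# y: phenotype records; recIdx: animal row (1..n) of each record; X: fixed
# design (dense or sparse); HinvList: one sparse/dense Hinv per genetic
# component; lambdas: varE / varG_k.
.assembleMME <- function(y, X, recIdx, n, HinvList, lambdas) {
  N <- length(y)
  Xs <- methods::as(X, "CsparseMatrix")
  Z <- Matrix::sparseMatrix(i = seq_len(N), j = recIdx, x = 1,
                            dims = c(N, n))
  K <- length(HinvList)
  W <- do.call(cbind, c(list(Xs), rep(list(Z), K)))
  D <- Matrix::bdiag(c(list(Matrix::Diagonal(ncol(Xs), 0)),
                       lapply(seq_len(K), function(k)
                         lambdas[k] * methods::as(HinvList[[k]],
                                                  "CsparseMatrix"))))
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) + D)
  list(C = C, rhs = as.numeric(Matrix::crossprod(W, y)), W = W,
       p = ncol(Xs), K = K, n = n)
}

# fixed-effect design for a generation factor; first level absorbed into
# the intercept (single-level factors collapse to the intercept)
.fixedDesign <- function(fixed, N) {
  fixed <- droplevels(as.factor(fixed))
  if (nlevels(fixed) < 2) return(matrix(1, N, 1,
                                        dimnames = list(NULL,
                                                        "(Intercept)")))
  stats::model.matrix(~fixed)
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems
.pcg <- function(C, b, tol = 1e-12, maxIter = 5000, x0 = NULL) {
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.numeric(C %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  it <- 0L
  repeat {
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol || it >= maxIter) break
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
    it <- it + 1L
  }
  list(x = x, iterations = it, residual = sqrt(sum(r^2)) / bnorm,
       converged = sqrt(sum(r^2)) / bnorm <= tol)
}

#' Solve the single-step mixed-model equations
#'
#' Animal model \code{y = Xb + Zu + e} (one genetic component) or
#' \code{y = Xb + Zu1 + Zu2 + e} (two uncorrelated components with their
#' own H matrices). The equations are solved either by Jacobi-
#' preconditioned conjugate gradient (default) or by a direct sparse
#' factorisation; GEBVs of animals without phenotypes (e.g. validation
#' animals) propagate through the H structure.
#'
#' @param y phenotype vector (training records only).
#' @param fixed factor of fixed-effect classes per record (generation); the
#'   first level is absorbed into the intercept.
#' @param recIds animal id per record.
#' @param ids all animal ids, defining the random-effect order.
#' @param HinvList list of 1 or 2 inverse relationship matrices (sparse,
#'   over all \code{ids}).
#' @param varG genetic variance per component.
#' @param varE residual variance.
#' @param method \code{"pcg"} or \code{"direct"}.
#' @param tol relative-residual convergence tolerance of the PCG
#'   (default 1e-12).
#' @param maxIter PCG iteration cap (default 5000).
#' @return A \linkS4class{SolveReport}; \code{gebv} is \code{u} or
#'   \code{u1 + u2}.
#' @export
solveMME <- function(y, fixed, recIds, ids, HinvList, varG, varE,
                     method = c("pcg", "direct"), tol = 1e-12,
                     maxIter = 5000) {
  method <- match.arg(method)
  if (!is.list(HinvList)) HinvList <- list(HinvList)
  K <- length(HinvList)
  stopifnot(length(varG) == K, varE > 0)
  recIdx <- match(recIds, ids)
  if (anyNA(recIdx)) stop("record ids missing from the animal id vector")
  X <- .fixedDesign(fixed, length(y))
  n <- length(ids)
  lambdas <- ifelse(varG > 0, varE / varG, Inf)
  # a vanishing genetic variance shrinks u to 0; cap lambda to stay finite
  lambdas[!is.finite(lambdas)] <- 1e12
  mme <- .assembleMME(y, X, recIdx, n, HinvList, lambdas)
  if (method == "pcg") {
    sol <- .pcg(mme$C, mme$rhs, tol = tol, maxIter = maxIter)
    theta <- sol$x
    iters <- sol$iterations
    converged <- sol$converged
    resid <- sol$residual
  } else {
    ch <- Cholesky(mme$C, LDL = FALSE)
    theta <- as.numeric(Matrix::solve(ch, mme$rhs))
    iters <- 1L
    resid <- sqrt(sum((mme$rhs - as.numeric(mme$C %*% theta))^2)) /
      max(sqrt(sum(mme$rhs^2)), 1e-300)
    converged <- TRUE
  }
  p <- mme$p
  u <- matrix(theta[-seq_len(p)], nrow = n, ncol = K)
  new("SolveReport", fixed = setNames(theta[seq_len(p)], colnames(X)),
      u = u, gebv = rowSums(u), ids = as.integer(ids),
      iterations = as.integer(iters), converged = converged,
      finalResidualNorm = resid)
}
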