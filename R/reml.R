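# REML variance-component estimation for the single- and two-component
# animal models: exact profiled-likelihood maximisation on the sparse MME
# (default), and average-information REML with EM fallback.

# -2 * restricted log-likelihood, profiled over the residual variance, as a
# function of the variance ratios lambda_k = varE / varG_k. Derived from
# the mixed-model-equation form: for C(lambda) = W'W + blockdiag(0,
# lambda_k Hinv_k),
#   -2 lR = (n - p) log sigmaE^2 + SSR / sigmaE^2 - sum_k q_k log lambda_k
#           + log|C(lambda)| + const,
# with SSR = y'y - theta_hat' W'y and the profiled sigmaE^2 = SSR/(n - p).
.remlProfileObjective <- function(loglam, y, X, recIdx, n, HinvList) {
  lambdas <- exp(loglam)
  K <- length(HinvList)
  mme <- .assembleMME(y, X, recIdx, n, HinvList, lambdas)
  ch <- tryCatch(Cholesky(mme$C, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf))
  theta <- as.numeric(Matrix::solve(ch, mme$rhs))
  SSR <- max(sum(y^2) - sum(theta * mme$rhs), 1e-12)
  np <- length(y) - mme$p
  sigE <- SSR / np
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  val <- np * (log(sigE) + 1) - n * sum(loglam) + logdetC
  list(value = val, sigE = sigE, lambdas = lambdas, theta = theta,
       p = mme$p)
}

# exact traces tr(Hinv_k C^{kk}) etc. via a dense inverse of the
# lambda-scaled coefficient matrix; only used by the AI/EM methods
.remlDenseInfo <- function(y, X, recIdx, n, HinvList, varG, varE) {
  K <- length(HinvList)
  lambdas <- varE / varG
  mme <- .assembleMME(y, X, recIdx, n, HinvList, lambdas)
  if (nrow(mme$C) > 8000)
    stop("dense AI/EM trace terms are limited to ~8000 equations; ",
         "use method = \"profile\"")
  Cd <- as.matrix(mme$C)
  ch <- tryCatch(chol(Cd), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Cinv <- chol2inv(ch)
  theta <- as.numeric(Cinv %*% mme$rhs)
  p <- mme$p
  e <- y - as.numeric(mme$W %*% theta)
  uList <- lapply(seq_len(K), function(k)
    theta[p + (k - 1) * n + seq_len(n)])
  trHC <- vapply(seq_len(K), function(k) {
    idx <- p + (k - 1) * n + seq_len(n)
    sum(as.matrix(HinvList[[k]]) * Cinv[idx, idx])
  }, 0)
  list(theta = theta, e = e, uList = uList, trHC = trHC, p = p,
       Cinv = Cinv, W = mme$W, C = mme$C, lambdas = lambdas)
}

#' Estimate variance components by REML
#'
#' Animal model with one or two genetic components (each with its own
#' relationship structure \code{Hinv}) plus a residual. Three equivalent
#' routes to the same REML maximum are available:
#' \describe{
#'   \item{\code{"profile"}}{(default) exact derivative-free maximisation
#'     of the restricted likelihood profiled over the residual variance,
#'     evaluated through sparse Cholesky factorisations of the mixed-model
#'     equations; scales to the pipeline's population sizes.}
#'   \item{\code{"ai"}}{average-information REML with exact trace terms
#'     (dense factorisation) and an EM fallback whenever an AI update
#'     leaves the parameter space; intended for small to medium problems.}
#'   \item{\code{"em"}}{plain EM-REML (slow but monotone).}
#' }
#'
#' @param y phenotype records.
#' @param fixed fixed-effect factor per record (generation class).
#' @param recIds animal id per record.
#' @param ids all animal ids (random-effect order).
#' @param HinvList list of 1 or 2 sparse inverse relationship matrices.
#' @param method estimation route.
#' @param maxRounds iteration cap for \code{"ai"}/\code{"em"} (default 50).
#' @param tol convergence tolerance: maximum relative parameter change
#'   (\code{"ai"}/\code{"em"}) or relative likelihood tolerance mapped to
#'   the optimiser (\code{"profile"}); default 1e-8.
#' @param start optional starting values \code{c(varG..., varE)}; defaults
#'   to an even split of the phenotypic variance across components.
#' @return list with \code{varG} (length 1 or 2), \code{varE}, \code{h2}
#'   (total genetic over total), \code{converged}, \code{boundary},
#'   \code{rounds}, \code{method} and \code{minus2logLik} (up to an
#'   additive constant). Non-convergence is reported, not raised.
#' @export
estimateVarComps <- function(y, fixed, recIds, ids, HinvList,
                             method = c("profile", "ai", "em"),
                             maxRounds = 50, tol = 1e-8, start = NULL) {
  method <- match.arg(method)
  if (!is.list(HinvList)) HinvList <- list(HinvList)
  K <- length(HinvList)
  stopifnot(K %in% 1:2)
  recIdx <- match(recIds, ids)
  if (anyNA(recIdx)) stop("record ids missing from the animal id vector")
  X <- .fixedDesign(fixed, length(y))
  n <- length(ids)
  vy <- var(y)
  if (is.null(start)) start <- c(rep(vy / (2 * K), K), vy / 2)

  if (method == "profile") {
    # lambda bounds equivalent to component h2 in (5e-4, 0.9995)
    lo <- log((1 - 0.9995) / 0.9995)
    hi <- log(0.9995 / 5e-4)
    obj <- function(ll) .remlProfileObjective(ll, y, X, recIdx, n,
                                              HinvList)$value
    if (K == 1) {
      opt <- optimize(obj, c(lo, hi), tol = 1e-7)
      ll <- opt$minimum
      conv <- TRUE
    } else {
      st <- log(start[K + 1] / start[seq_len(K)])
      opt <- optim(st, function(ll) obj(pmin(pmax(ll, lo), hi)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 800))
      ll <- pmin(pmax(opt$par, lo), hi)
      conv <- opt$convergence == 0
    }
    fit <- .remlProfileObjective(ll, y, X, recIdx, n, HinvList)
    varE <- fit$sigE
    varG <- varE / fit$lambdas
    boundary <- any(abs(ll - lo) < 1e-6 | abs(ll - hi) < 1e-6)
    return(list(varG = varG, varE = varE,
                h2 = sum(varG) / (sum(varG) + varE),
                converged = conv, boundary = boundary,
                rounds = if (K == 1) NA_integer_ else opt$counts[1],
                method = method, minus2logLik = fit$value))
  }

  # ---- AI / EM in the variance scale --------------------------------
  thetaV <- start
  np <- length(y) - ncol(X)
  conv <- FALSE
  rounds <- 0L
  for (round in seq_len(maxRounds)) {
    rounds <- round
    info <- .remlDenseInfo(y, X, recIdx, n, HinvList,
                           varG = thetaV[seq_len(K)],
                           varE = thetaV[K + 1])
    if (is.null(info)) break
    varG <- thetaV[seq_len(K)]
    varE <- thetaV[K + 1]
    uHu <- vapply(seq_len(K), function(k)
      as.numeric(Matrix::crossprod(info$uList[[k]],
                                   HinvList[[k]] %*% info$uList[[k]])), 0)
    # EM updates (also the fallback step)
    emG <- vapply(seq_len(K), function(k)
      (uHu[k] + varE * info$trHC[k]) / n, 0)
    trWCW <- (ncol(X) + K * n) -
      sum(info$lambdas * info$trHC)
    emE <- (sum(info$e * y)) / np
    newTheta <- NULL
    if (method == "ai") {
      # scores
      trPV <- vapply(seq_len(K), function(k)
        (n - info$lambdas[k] * info$trHC[k]) / varG[k], 0)
      yPVPy <- uHu / varG^2
      Py <- info$e / varE
      trP <- (length(y) - ncol(X) - sum(n - info$lambdas * info$trHC)) /
        varE
      score <- c(-0.5 * (trPV - yPVPy),
                 -0.5 * (trP - sum(Py^2)))
      # AI matrix from working vectors f_k = V_k P y, f_e = P y
      Fmat <- cbind(vapply(seq_len(K), function(k) {
        Zu <- info$uList[[k]][recIdx] / varG[k]
        Zu
      }, numeric(length(y))), Py)
      PF <- apply(Fmat, 2, function(f) {
        th <- as.numeric(info$Cinv %*%
                           as.numeric(Matrix::crossprod(info$W, f)))
        (f - as.numeric(info$W %*% th)) / varE
      })
      AI <- 0.5 * crossprod(Fmat, PF)
      upd <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(upd)) {
        cand <- thetaV + as.numeric(upd)
        if (all(cand > 1e-8) && all(is.finite(cand)))
          newTheta <- cand
      }
    }
    if (is.null(newTheta)) newTheta <- c(emG, emE)
    newTheta <- pmax(newTheta, 1e-8)
    delta <- max(abs(newTheta - thetaV) / pmax(thetaV, 1e-8))
    thetaV <- newTheta
    if (delta < tol) { conv <- TRUE; break }
  }
  varG <- thetaV[seq_len(K)]
  varE <- thetaV[K + 1]
  ll <- log(varE / varG)
  fit <- .remlProfileObjective(ll, y, X, recIdx, n, HinvList)
  boundary <- any(varG < 1e-6 * vy)
  list(varG = varG, varE = varE, h2 = sum(varG) / (sum(varG) + varE),
       converged = conv, boundary = boundary, rounds = rounds,
       method = method, minus2logLik = fit$value)
}
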