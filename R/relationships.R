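# Pedigree and genomic relationship matrices: A, A inverse, A22, VanRaden
# G, blending, and the single-step H inverse.

# normalise pedigree input (Population or data.frame with id/sire/dam) to
# internal 1..n coding with parents preceding offspring; detects cycles
.pedInput <- function(ped) {
  if (is(ped, "Population")) ped <- ped@ped
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (anyDuplicated(ped$id)) stop("duplicated animal ids in pedigree")
  idx <- match(ped$sire, ped$id); idx[ped$sire == 0] <- 0L
  jdx <- match(ped$dam, ped$id); jdx[ped$dam == 0] <- 0L
  if (anyNA(idx) || anyNA(jdx))
    stop("pedigree refers to parents that have no own record")
  ord <- seq_len(n)
  if (any(idx >= ord & idx > 0) || any(jdx >= ord & jdx > 0)) {
    # topological sort (Kahn); fails on cycles
    indeg <- integer(n)
    kids <- vector("list", n)
    for (i in seq_len(n)) for (pp in c(idx[i], jdx[i])) if (pp > 0) {
      indeg[i] <- indeg[i] + 1L
      kids[[pp]] <- c(kids[[pp]], i)
    }
    queue <- which(indeg == 0L); ord <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ord <- c(ord, v)
      for (w in kids[[v]]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) queue <- c(queue, w)
      }
    }
    if (length(ord) < n) stop("pedigree contains a cycle")
    pos <- integer(n); pos[ord] <- seq_len(n)
    idx <- ifelse(idx > 0, pos[pmax(idx, 1L)], 0L)[ord]
    jdx <- ifelse(jdx > 0, pos[pmax(jdx, 1L)], 0L)[ord]
  }
  list(sire = as.integer(idx), dam = as.integer(jdx), ids = ped$id[ord],
       order = ord, n = n)
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' @param ped a \linkS4class{Population} or a pedigree data.frame with
#'   columns \code{id}, \code{sire}, \code{dam} (0 = unknown parent).
#' @return Named numeric vector of inbreeding coefficients (founders 0).
#' @export
pedigreeInbreeding <- function(ped) {
  p <- .pedInput(ped)
  Fv <- cpp_inbreeding(p$sire, p$dam)
  out <- numeric(p$n)
  out[p$order] <- Fv
  ids <- if (is(ped, "Population")) ped@ped$id else ped$id
  setNames(out, ids)
}

#' Pedigree relationship matrix by the tabular method
#'
#' Dense construction, intended for pedigrees up to a few thousand animals;
#' use \code{\link{aSubmatrix}} to extract the genotyped block of a large
#' pedigree.
#'
#' @param ped pedigree (see \code{\link{pedigreeInbreeding}}).
#' @param ids optional subset of animal ids: returns that block of A (e.g.
#'   A22 for the genotyped animals).
#' @return Dense numeric relationship matrix with ids as dimnames.
#' @export
aMatrix <- function(ped, ids = NULL) {
  p <- .pedInput(ped)
  n <- p$n
  if (n > 12000)
    stop("tabular A is dense; for ", n, " animals use aSubmatrix()")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0) A[j, s] else 0) +
                    (if (d > 0) A[j, d] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(p$ids, p$ids)
  if (!is.null(ids)) {
    k <- match(as.character(ids), rownames(A))
    if (anyNA(k)) stop("subset ids not present in the pedigree")
    A <- A[k, k, drop = FALSE]
  }
  A
}

#' Sparse inverse pedigree relationship matrix (Henderson's rules with
#' inbreeding)
#'
#' @param ped pedigree (see \code{\link{pedigreeInbreeding}}).
#' @return A sparse symmetric \code{Matrix} in the pedigree's row order.
#' @export
aInverse <- function(ped) {
  p <- .pedInput(ped)
  n <- p$n
  Fv <- cpp_inbreeding(p$sire, p$dam)
  s <- p$sire; d <- p$dam
  Fs <- ifelse(s > 0, Fv[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0, Fv[pmax(d, 1L)], 0)
  mend <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
                 ifelse(s > 0 | d > 0, 0.75 - 0.25 * (Fs + Fd), 1))
  al <- 1 / mend
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, al)
  for (pcol in list(s, d)) {
    has <- pcol > 0
    add(idx[has], pcol[has], -0.5 * al[has])
    add(pcol[has], idx[has], -0.5 * al[has])
    add(pcol[has], pcol[has], 0.25 * al[has])
  }
  both <- s > 0 & d > 0
  add(s[both], d[both], 0.25 * al[both])
  add(d[both], s[both], 0.25 * al[both])
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  # return in original row order
  inv <- integer(n); inv[p$order] <- seq_len(n)
  M <- M[inv, inv]
  dimnames(M) <- list(as.character(if (is(ped, "Population")) ped@ped$id
                                   else ped$id),
                      as.character(if (is(ped, "Population")) ped@ped$id
                                   else ped$id))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationships among a subset (A22) of a large pedigree
#'
#' Computed indirectly as columns of A obtained by sparse solves with the
#' inverse relationship matrix, which avoids the dense tabular A.
#'
#' @param ped pedigree.
#' @param ids the subset (e.g. genotyped animals).
#' @return Dense relationship block among \code{ids}.
#' @export
aSubmatrix <- function(ped, ids) {
  pd <- if (is(ped, "Population")) ped@ped else ped
  k <- match(ids, pd$id)
  if (anyNA(k)) stop("subset ids not present in the pedigree")
  Ainv <- aInverse(ped)
  n <- nrow(Ainv)
  E <- matrix(0, n, length(k))
  E[cbind(k, seq_along(k))] <- 1
  ch <- Cholesky(Matrix::forceSymmetric(Ainv), LDL = FALSE)
  cols <- as.matrix(Matrix::solve(ch, E))
  A22 <- cols[k, , drop = FALSE]
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ids, ids)
  A22
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' \code{G = M M' / (2 * sum(p_i (1 - p_i)))} with \code{M} the dosage
#' matrix centred by twice the allele frequency. Frequencies default to the
#' current genotyped set; missing dosages are mean-imputed (\code{2p})
#' before centring.
#'
#' @param geno a \linkS4class{GenotypeData} or a dosage matrix
#'   (individuals x markers, NA = missing).
#' @param freq optional fixed allele frequencies.
#' @return Dense G with attributes \code{"freq"} and \code{"scale"}.
#' @export
gMatrix <- function(geno, freq = NULL) {
  d <- if (is(geno, "GenotypeData")) geno@dosages else geno
  if (is.null(freq)) freq <- colMeans(d, na.rm = TRUE) / 2
  if (anyNA(d)) {
    imp <- rep(2 * freq, each = nrow(d))
    d[is.na(d)] <- imp[is.na(d)]
  }
  sc <- 2 * sum(freq * (1 - freq))
  if (sc <= 0)
    stop("all markers are monomorphic; the VanRaden scale is zero")
  M <- sweep(d, 2, 2 * freq)
  G <- tcrossprod(M) / sc
  if (is(geno, "GenotypeData")) dimnames(G) <- list(geno@ids, geno@ids)
  attr(G, "freq") <- freq
  attr(G, "scale") <- sc
  G
}

#' Blend G with A22 and invert
#'
#' \code{Gb = alpha * G + beta * A22} (defaults 0.95/0.05); positive
#' definiteness is verified before inversion.
#'
#' @param G raw genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped animals, same order.
#' @param alpha,beta blending weights; \code{beta} defaults to
#'   \code{1 - alpha}.
#' @return list(Gb, GbInv, alpha, beta).
#' @export
blendGMatrix <- function(G, A22, alpha = 0.95, beta = 1 - alpha) {
  if (!all(dim(G) == dim(A22)))
    stop("G and A22 are not conformable")
  Gb <- alpha * G + beta * A22
  ch <- tryCatch(chol(Gb), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "blended G is not positive definite (smallest eigenvalue %.3e); %s",
      ev, "increase beta"))
  }
  GbInv <- chol2inv(ch)
  dimnames(GbInv) <- dimnames(Gb)
  list(Gb = Gb, GbInv = GbInv, alpha = alpha, beta = beta)
}

#' Single-step H inverse
#'
#' \code{H^-1 = A^-1 + [0 0; 0 tau * Gb^-1 - omega * A22^-1]} on the
#' genotyped block.
#'
#' @param Ainv sparse inverse pedigree relationship matrix (all animals).
#' @param A22inv dense inverse of the genotyped pedigree block.
#' @param GbInv inverse blended genomic relationship matrix.
#' @param genoIdx row positions (in \code{Ainv}) of the genotyped animals,
#'   in the order of \code{GbInv}.
#' @param tau,omega weighting factors (defaults 1).
#' @return Sparse symmetric H inverse.
#' @export
hInverse <- function(Ainv, A22inv, GbInv, genoIdx, tau = 1, omega = 1) {
  n <- nrow(Ainv)
  q <- length(genoIdx)
  if (!all(dim(GbInv) == q) || !all(dim(A22inv) == q))
    stop("genotyped block dimensions do not match genoIdx")
  if (any(genoIdx < 1 | genoIdx > n)) stop("genoIdx out of range")
  aug <- tau * GbInv - omega * A22inv
  Aug <- Matrix::sparseMatrix(i = rep(genoIdx, times = q),
                              j = rep(genoIdx, each = q),
                              x = as.numeric(aug), dims = c(n, n))
  Matrix::forceSymmetric(Matrix::drop0(Ainv + Aug, tol = 0))
}

#' Compatibility statistics between the blended G and A22
#'
#' Correlations of the diagonal, off-diagonal and all elements, summary of
#' the G diagonal, and a flag raised when the off-diagonal correlation
#' falls below \code{minCor} (poor genomic information; the corresponding
#' prediction scenario is skipped).
#'
#' @param Gb,A22 matrices over the same animals in the same order.
#' @param minCor flag threshold (default 0.30).
#' @return list of statistics with element \code{poor}.
#' @export
compatibilityStats <- function(Gb, A22, minCor = 0.30) {
  stopifnot(all(dim(Gb) == dim(A22)))
  off <- upper.tri(Gb)
  corOr1 <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    sx <- sd(x); sy <- sd(y)
    if (sx == 0 && sy == 0)
      return(if (isTRUE(all.equal(as.numeric(x), as.numeric(y)))) 1
             else NA_real_)
    if (sx == 0 || sy == 0) return(NA_real_)
    cor(x, y)
  }
  dcor <- corOr1(diag(Gb), diag(A22))
  ocor <- corOr1(Gb[off], A22[off])
  acor <- corOr1(c(Gb), c(A22))
  list(cor_diag = dcor, cor_offdiag = ocor, cor_all = acor,
       g_diag_mean = mean(diag(Gb)), g_diag_min = min(diag(Gb)),
       g_diag_max = max(diag(Gb)),
       poor = is.na(ocor) || ocor < minCor, min_cor = minCor)
}

#' Assemble the relationship set for a single-step evaluation
#'
#' @param ped pedigree (all animals).
#' @param geno a \linkS4class{GenotypeData} for the genotyped animals.
#' @param alpha,beta,tau,omega blending/weighting parameters.
#' @return A \linkS4class{RelationshipSet}.
#' @export
buildRelationships <- function(ped, geno, alpha = 0.95, beta = 1 - alpha,
                               tau = 1, omega = 1) {
  pd <- if (is(ped, "Population")) ped@ped else ped
  genoIdx <- match(geno@ids, pd$id)
  if (anyNA(genoIdx)) stop("genotyped ids missing from the pedigree")
  Ainv <- aInverse(ped)
  A22 <- aSubmatrix(ped, geno@ids)
  G <- gMatrix(geno)
  bl <- blendGMatrix(G, A22, alpha, beta)
  A22inv <- chol2inv(chol(A22))
  Hinv <- hInverse(Ainv, A22inv, bl$GbInv, genoIdx, tau, omega)
  new("RelationshipSet", Ainv = Ainv, A22 = A22, G = G, Gb = bl$Gb,
      GbInv = bl$GbInv, Hinv = Hinv, genoIds = as.integer(geno@ids),
      alpha = alpha, beta = beta, tau = tau, omega = omega)
}
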