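densemme <- function(y, gen, recIdx, n, Hinvs, varG, varE) {
  X <- model.matrix(~factor(gen))
  Z <- matrix(0, length(y), n)
  Z[cbind(seq_along(y), recIdx)] <- 1
  W <- do.call(cbind, c(list(X), rep(list(Z), length(Hinvs))))
  D <- matrix(0, ncol(W), ncol(W))
  off <- ncol(X)
  for (k in seq_along(Hinvs)) {
    idx <- off + seq_len(n)
    D[idx, idx] <- (varE / varG[k]) * as.matrix(Hinvs[[k]])
    off <- off + n
  }
  solve(crossprod(W) + D, crossprod(W, y))
}

test_that("PCG matches a dense direct solve of the MME", {
  set.seed(10)
  ped <- data.frame(id = 1:20, sire = c(rep(0, 6), sample(1:3, 14, TRUE)),
                    dam = c(rep(0, 6), sample(4:6, 14, TRUE)))
  Ainv <- aInverse(ped)
  y <- rnorm(20, 50, 5)
  gen <- rep(1:4, each = 5)
  sol <- solveMME(y, gen, 1:20, 1:20, Ainv, varG = 10, varE = 30)
  ref <- densemme(y, gen, 1:20, 20, list(Ainv), 10, 30)
  expect_lt(max(abs(c(sol@fixed, sol@u) - ref)), 1e-8)
  expect_true(sol@converged)
  # direct sparse route agrees too
  sold <- solveMME(y, gen, 1:20, 1:20, Ainv, varG = 10, varE = 30,
                   method = "direct")
  expect_lt(max(abs(sold@gebv - sol@gebv)), 1e-8)
  # determinism: same inputs, same solution
  sol2 <- solveMME(y, gen, 1:20, 1:20, Ainv, varG = 10, varE = 30)
  expect_identical(sol@gebv, sol2@gebv)
})

test_that("vanishing genetic variance shrinks all GEBVs to zero", {
  set.seed(11)
  ped <- data.frame(id = 1:15, sire = c(rep(0, 5), sample(1:2, 10, TRUE)),
                    dam = c(rep(0, 5), sample(3:5, 10, TRUE)))
  y <- rnorm(15)
  sol <- solveMME(y, rep(1, 15), 1:15, 1:15, aInverse(ped),
                  varG = 1e-10, varE = 1)
  expect_lt(max(abs(sol@gebv)), 1e-4)
})

test_that("H inverse = A inverse recovers pedigree BLUP; all-genotyped
          ssGBLUP equals GBLUP", {
  set.seed(12)
  # pedigree reduction
  ped <- data.frame(id = 1:30, sire = c(rep(0, 8), sample(1:4, 22, TRUE)),
                    dam = c(rep(0, 8), sample(5:8, 22, TRUE)))
  Ainv <- aInverse(ped)
  y <- rnorm(30, 20, 4)
  gen <- rep(1:3, each = 10)
  sol <- solveMME(y, gen, 1:30, 1:30, Ainv, varG = 8, varE = 24)
  ref <- densemme(y, gen, 1:30, 30, list(Ainv), 8, 24)
  expect_lt(max(abs(sol@gebv - ref[-(1:3)])), 1e-8)
  # all animals genotyped, alpha = 1, tau = omega = 1: ssGBLUP == GBLUP
  n <- 40
  d <- matrix(rbinom(n * 400, 2, 0.5), n, 400)  # markers >> animals
  ped2 <- data.frame(id = 1:n, sire = 0, dam = 0)
  # centring by fixed base frequencies keeps G positive definite (data-
  # frequency centring leaves the ones vector in the null space)
  G <- gMatrix(d, freq = rep(0.5, 400))
  Gi <- solve(G)
  Hinv <- hInverse(aInverse(ped2), solve(aMatrix(ped2)), Gi, 1:n,
                   tau = 1, omega = 1)
  y2 <- rnorm(n)
  solH <- solveMME(y2, rep(1, n), 1:n, 1:n, Hinv, varG = 5, varE = 10)
  # GBLUP reference: dense MME with G inverse directly
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + 2 * Gi))
  ref2 <- solve(C, c(crossprod(X, y2), y2))
  expect_lt(max(abs(solH@gebv - ref2[-1])), 1e-6)
})

test_that("profile, AI and EM REML agree at the same maximum", {
  b <- tinyBreed(201, ebvGens = 2, phenGens = 2)
  ped <- pedigree(b$pop)
  y <- phenotypes(b$pop); ok <- !is.na(y)
  Ainv <- aInverse(b$pop)
  vp <- estimateVarComps(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                         list(Ainv), method = "profile")
  va <- estimateVarComps(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                         list(Ainv), method = "ai", tol = 1e-8)
  expect_true(va$converged)
  expect_equal(va$varG, vp$varG, tolerance = 1e-3)
  expect_equal(va$varE, vp$varE, tolerance = 1e-3)
  ve <- estimateVarComps(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                         list(Ainv), method = "em", tol = 1e-5,
                         maxRounds = 400)
  expect_equal(ve$h2, vp$h2, tolerance = 0.02)
})

test_that("REML recovers a simulated heritability and flags pure noise",
          {
  cfg <- tinyConfig(nHD = 60, nMed = 20, nQTL = 10)
  th <- tinyHistorical(211, cfg = cfg, census = 200, gens = 10)
  mc <- matingConfig(maxDams = 80, femaleGrowth = 0.15)
  b <- foundBreed(th$pop, 150, "R", seed = 1)
  b <- runRecentSelection(b, 4, mode = "random", mating = mc,
                          trait = th$trait, seed = 2)
  ped <- pedigree(b); y <- phenotypes(b); ok <- !is.na(y)
  Ainv <- aInverse(b)
  v <- estimateVarComps(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                        list(Ainv))
  expect_lt(abs(v$h2 - 0.30), 0.09)
  # pure noise: genetic variance at the boundary near zero
  set.seed(3)
  ynoise <- rnorm(sum(ok), 0, 10)
  v0 <- estimateVarComps(ynoise, ped$generation[ok], ped$id[ok], ped$id,
                         list(Ainv))
  expect_lt(v0$h2, 0.05)
})

test_that("two-component model: order symmetry and degenerate flatness",
          {
  b <- tinyBreed(221, ebvGens = 2, phenGens = 1)
  pop <- b$pop; ped <- pedigree(pop)
  ids <- tail(ped$id, 80)
  g <- applyGenotyping(pop, ids, "medium", 0, 0)
  d <- dosages(g)
  d1 <- d[, 1:50]; d2 <- d[, 51:110]
  Ainv <- aInverse(pop)
  A22 <- aSubmatrix(pop, ids)
  A22i <- chol2inv(chol(A22))
  idx <- match(ids, ped$id)
  mkH <- function(dd) {
    bl <- blendGMatrix(gMatrix(dd), A22)
    hInverse(Ainv, A22i, bl$GbInv, idx)
  }
  H1 <- mkH(d1); H2 <- mkH(d2)
  y <- phenotypes(pop); ok <- !is.na(y)
  s12 <- solveMME(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                  list(H1, H2), varG = c(10, 12), varE = 70)
  s21 <- solveMME(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                  list(H2, H1), varG = c(12, 10), varE = 70)
  expect_lt(max(abs(s12@gebv - s21@gebv)), 1e-7)
  # duplicated marker sets leave the likelihood flat: AI-REML must flag
  vdup <- estimateVarComps(y[ok], ped$generation[ok], ped$id[ok], ped$id,
                           list(H1, H1), method = "ai", maxRounds = 15)
  expect_true(!vdup$converged || vdup$boundary ||
                abs(vdup$varG[1] - vdup$varG[2]) / sum(vdup$varG) > 0.5)
})
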