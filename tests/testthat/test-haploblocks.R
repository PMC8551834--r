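# helper: phased haplotypes with planted LD structure. Blocks are planted
# by duplicating a template column (perfect LD) and independent SNPs are
# fresh Bernoulli draws.
plantedHap <- function(n, spec, seed = 1) {
  # spec: list of integers; positive k plants a k-SNP island of identical
  # columns, 0 plants one independent SNP
  set.seed(seed)
  cols <- list()
  for (s in spec) {
    if (s == 0) {
      cols[[length(cols) + 1]] <- rbinom(n, 1, 0.5)
    } else {
      tmpl <- rbinom(n, 1, 0.5)
      for (k in seq_len(s)) cols[[length(cols) + 1]] <- tmpl
    }
  }
  h <- do.call(cbind, cols)
  # guard against monomorphic draws
  h[1, ] <- 0; h[2, ] <- 1
  h
}

lociFor <- function(h) data.frame(chrom = 1, pos_bp = seq_len(ncol(h)),
                                  pos_cM = seq_len(ncol(h)) * 1e-6)

test_that("all-coupled SNPs form one block; independent SNPs form none", {
  h <- plantedHap(60, list(5))
  bl <- buildLDBlocks(h, lociFor(h), 0.6)
  expect_equal(nrow(blockTable(bl)), 1)
  expect_equal(blockTable(bl)$n_snps, 5)
  h0 <- plantedHap(400, list(0, 0, 0, 0, 0, 0), seed = 3)
  bl0 <- buildLDBlocks(h0, lociFor(h0), 0.3)
  expect_equal(nrow(blockTable(bl0)), 0)
})

test_that("two planted islands are recovered exactly", {
  h <- plantedHap(300, list(3, 0, 0, 3), seed = 7)
  bl <- buildLDBlocks(h, lociFor(h), 0.6)
  expect_equal(nrow(blockTable(bl)), 2)
  expect_equal(bl@members, list(1:3, 6:8))
})

test_that("the interval selection matches exhaustive enumeration on
          8-SNP maps", {
  set.seed(11)
  for (rep in 1:12) {
    n <- 80
    h <- matrix(rbinom(8 * n, 1, 0.5), n, 8)
    # induce some correlation between neighbours at random
    for (j in 2:8) if (runif(1) < 0.6) {
      keep <- runif(n) < runif(1, 0.5, 1)
      h[keep, j] <- h[keep, j - 1]
    }
    h[1, ] <- 0; h[2, ] <- 1
    thr <- sample(c(0.1, 0.3, 0.6), 1)
    got <- buildLDBlocks(h, lociFor(h), thr, windowSnps = 8)
    r2m <- cor(h)^2
    want <- blockBruteForce(r2m, thr, window = 8)
    gotM <- if (length(got@members))
      do.call(rbind, lapply(got@members, range)) else
        matrix(integer(0), 0, 2)
    expect_equal(unname(gotM), unname(want), ignore_attr = TRUE,
                 label = paste("rep", rep, "thr", thr))
  }
})

test_that("unphased input and bad thresholds are rejected", {
  h <- matrix(sample(0:2, 40, TRUE), 10, 4)
  expect_error(buildLDBlocks(h, lociFor(h), 0.3), "phased")
  h2 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_error(buildLDBlocks(h2, lociFor(h2), 0), "in \\(0, 1\\)")
})

test_that("raising the threshold never increases the number of blocked
          SNPs", {
  b <- tinyBreed(111, ebvGens = 2, phenGens = 2)$pop
  lo <- lociInfo(b)
  mr <- which(lo$medium)
  cols1 <- hapstep:::hapColOf(b, b@haploIds)
  cols <- as.vector(rbind(cols1, cols1 + 1L))
  hap <- t(matrix(as.integer(b@haplo[mr, cols]), length(mr)))
  loci <- lo[mr, ]
  prev <- Inf
  for (thr in c(0.1, 0.3, 0.6)) {
    bl <- buildLDBlocks(hap, loci, thr, windowSnps = 40)
    nb <- sum(blockTable(bl)$n_snps)
    expect_lte(nb, prev)
    prev <- nb
  }
})

test_that("pseudo-SNP encoding: one locus per allele, dosages sum to 2", {
  # construct a 2-SNP block with known haplotypes for 4 individuals
  hap <- rbind(c(0, 0), c(0, 1), c(0, 1), c(1, 1),
               c(0, 0), c(0, 0), c(1, 1), c(1, 0))
  bl <- new("HaploblockSet",
            blocks = data.frame(chrom = 1, start_bp = 1, end_bp = 2,
                                n_snps = 2, threshold = 0.3),
            members = list(1:2), loci = lociFor(hap), threshold = 0.3,
            windowSnps = 10)
  ps <- encodePseudoSNPs(hap, bl, ids = 1:4)
  expect_equal(ncol(dosages(ps)), 4)  # alleles 00, 01, 10, 11
  expect_equal(sort(ps@alleleLabel), c("00", "01", "10", "11"))
  expect_true(all(rowSums(dosages(ps)) == 2))
  # individual 3 is homozygous "00": dosage 2 there, 0 elsewhere
  d3 <- dosages(ps)[3, ]
  expect_equal(unname(d3[ps@alleleLabel == "00"]), 2)
  expect_equal(sum(d3), 2)
  # monomorphic block: a single pseudo-locus with all dosages 2
  hapm <- matrix(0, 8, 2)
  psm <- encodePseudoSNPs(hapm, bl, ids = 1:4)
  expect_equal(ncol(dosages(psm)), 1)
  expect_true(all(dosages(psm) == 2))
})

test_that("five distinct haplotype alleles give five pseudo-loci", {
  # 3-SNP block, alleles 000 001 010 100 111 distributed over 10 inds
  alleles <- c("000", "001", "010", "100", "111")
  gam <- alleles[c(1, 1, 2, 3, 1, 4, 5, 5, 2, 2, 3, 1, 4, 1, 5, 2, 1, 3,
                   2, 4)]
  hap <- do.call(rbind, lapply(strsplit(gam, ""), as.integer))
  bl <- new("HaploblockSet",
            blocks = data.frame(chrom = 1, start_bp = 1, end_bp = 3,
                                n_snps = 3, threshold = 0.3),
            members = list(1:3), loci = lociFor(hap), threshold = 0.3,
            windowSnps = 10)
  ps <- encodePseudoSNPs(hap, bl, ids = 1:10)
  expect_equal(ncol(dosages(ps)), 5)
  expect_setequal(ps@alleleLabel, alleles)
  expect_true(all(rowSums(dosages(ps)) == 2))
})

test_that("missing phase inside a block is mean-imputed and flagged", {
  hap <- rbind(c(0, 0), c(1, 1), c(0, 0), c(0, 0), c(NA, 0), c(1, 1))
  bl <- new("HaploblockSet",
            blocks = data.frame(chrom = 1, start_bp = 1, end_bp = 2,
                                n_snps = 2, threshold = 0.3),
            members = list(1:2), loci = lociFor(hap), threshold = 0.3,
            windowSnps = 10)
  ps <- encodePseudoSNPs(hap, bl, ids = 1:3)
  expect_equal(attr(ps, "imputed"), 1L)
  expect_equal(unname(rowSums(dosages(ps))), rep(2, 3))
})

test_that("pseudo-SNP QC mirrors the SNP rules", {
  set.seed(21)
  n <- 500
  mkPs <- function(d, labels) {
    new("PseudoSNPMatrix", dosages = d, ids = seq_len(nrow(d)),
        loci = data.frame(chrom = 1, pos_cM = NA,
                          pos_bp = seq_len(ncol(d)),
                          id = paste0("PS_", seq_len(ncol(d)))),
        panel = "pseudo", block = rep(1L, ncol(d)),
        alleleLabel = labels)
  }
  common <- function() rbinom(n, 2, 0.5)
  rare <- c(rep(0, n - 2), 1, 1)  # freq 0.002
  d <- cbind(common(), rare, common())
  ps <- mkPs(d, c("a", "b", "c"))
  q <- qcPseudoSNPs(ps)
  expect_equal(ncol(dosages(q)), 2)
  expect_equal(q@alleleLabel, c("a", "c"))
  # a fixture with 20 pseudo-loci of which 7 are rare keeps 13
  d20 <- do.call(cbind, c(replicate(13, common(), simplify = FALSE),
                          replicate(7, rare, simplify = FALSE)))
  q20 <- qcPseudoSNPs(mkPs(d20, paste0("x", 1:20)))
  expect_equal(ncol(dosages(q20)), 13)
})

test_that("block summary arithmetic", {
  expect_equal(blockSummary(NULL, NULL, NULL, 964)$
                 n_nonblocked_plus_pseudo_after_qc, 964)
  # one 3-SNP block with 4 surviving alleles on a 10-SNP panel
  hap <- plantedHap(40, list(3, 0, 0, 0, 0, 0, 0, 0), seed = 2)
  bl <- new("HaploblockSet",
            blocks = data.frame(chrom = 1, start_bp = 1, end_bp = 3,
                                n_snps = 3, threshold = 0.3),
            members = list(1:3), loci = lociFor(hap), threshold = 0.3,
            windowSnps = 10)
  fakePs <- function(k) new("PseudoSNPMatrix",
    dosages = matrix(1, 5, k), ids = 1:5,
    loci = data.frame(chrom = 1, pos_cM = NA, pos_bp = 1:k,
                      id = paste0("PS_", 1:k)),
    panel = "pseudo", block = rep(1L, k), alleleLabel = paste0("a", 1:k))
  s <- blockSummary(bl, fakePs(4), fakePs(4), nIndependentSnps = 7)
  expect_equal(unlist(s[, 1:5], use.names = FALSE), c(1, 3, 4, 4, 11))
  expect_gte(s$n_blocked_snps, 2 * s$n_blocks)
})

test_that("dosage conservation holds after encoding and bounded after
          QC", {
  b <- tinyBreed(131, ebvGens = 2, phenGens = 1)$pop
  lo <- lociInfo(b)
  mr <- which(lo$medium)
  ids <- tail(b@haploIds, 60)
  cols1 <- hapstep:::hapColOf(b, ids)
  cols <- as.vector(rbind(cols1, cols1 + 1L))
  hap <- t(matrix(as.integer(b@haplo[mr, cols]), length(mr)))
  bl <- buildLDBlocks(hap, lo[mr, ], 0.3, windowSnps = 40)
  if (nrow(blockTable(bl)) > 0) {
    ps <- encodePseudoSNPs(hap, bl, ids)
    for (bk in unique(ps@block)) {
      sums <- rowSums(dosages(ps)[, ps@block == bk, drop = FALSE])
      expect_true(all(abs(sums - 2) < 1e-9))
    }
    q <- qcPseudoSNPs(ps)
    if (ncol(dosages(q)) > 0)
      for (bk in unique(q@block)) {
        sums <- rowSums(dosages(q)[, q@block == bk, drop = FALSE])
        expect_true(all(sums <= 2 + 1e-9))
      }
  }
  succeed()
})
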