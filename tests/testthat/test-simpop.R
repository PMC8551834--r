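test_that("genome sampling places disjoint markers and QTLs and is
          deterministic under a seed", {
  cfg <- genomeConfig(c(100, 100), nMarkersHD = 100, nMarkersMedium = 40,
                      nQTL = 10, nMarkerCandidates = 100,
                      nQTLCandidates = 10)
  a1 <- sampleGenomeArchitecture(cfg, seed = 5)
  a2 <- sampleGenomeArchitecture(cfg, seed = 5)
  expect_identical(a1$map@loci, a2$map@loci)
  expect_identical(a1$trait@effects, a2$trait@effects)
  lo <- a1$map@loci
  expect_equal(nrow(lo), 110)
  for (ch in unique(lo$chrom))
    expect_false(anyDuplicated(lo$pos_bp[lo$chrom == ch]) > 0)
  expect_true(all(lo$n_alleles[lo$type == "qtl"] %in% 2:6))
  # variance partition: h2 0.30, qtlH2 0.15, varP 100 -> polygenic 15
  expect_equal(a1$trait@varPolygenic, 15)
  # too many loci for the resolution is rejected
  tiny <- genomeConfig(data.frame(chrom = 1, length_cM = 1e-4),
                       nMarkersHD = 50, nMarkersMedium = 10, nQTL = 60,
                       nMarkerCandidates = 50, nQTLCandidates = 60)
  expect_error(sampleGenomeArchitecture(tiny, seed = 1),
               "distinguishable")
})

test_that("trait calibration hits the target QTL variance in the founder
          generation", {
  th <- tinyHistorical(17)
  bv <- hapstep:::.qtlBV(th$pop, th$trait, th$pop@haploIds)
  expect_equal(var(bv), 0.15 * 100, tolerance = 1e-8)
})

test_that("heterozygosity decays like a Wright-Fisher population", {
  cfg <- genomeConfig(data.frame(chrom = 1, length_cM = 10),
                      nMarkersHD = 2, nMarkersMedium = 1, nQTL = 1,
                      nMarkerCandidates = 4, nQTLCandidates = 1,
                      markerMutationRate = 0, qtlMutationRate = 0)
  arch <- sampleGenomeArchitecture(cfg, seed = 1)
  N <- 20; tgen <- 10
  sched <- data.frame(gen = c(0, tgen), census = c(N, N))
  set.seed(99)
  hets <- replicate(250, {
    h <- simulateHistorical(arch$map, cfg, sched)
    lo <- lociInfo(h)
    r <- which(lo$type == "marker")
    p <- rowMeans(matrix(as.integer(haplotypes(h)[r, ]), length(r)))
    mean(2 * p * (1 - p))
  })
  expected <- 0.5 * (1 - 1 / (2 * N))^tgen
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se + 0.01)
})

test_that("a bottleneck raises r2 at a fixed distance relative to a
          constant-size control", {
  cfg <- genomeConfig(data.frame(chrom = 1, length_cM = 50),
                      nMarkersHD = 60, nMarkersMedium = 20, nQTL = 2,
                      nMarkerCandidates = 80, nQTLCandidates = 4,
                      markerMutationRate = 0, qtlMutationRate = 0)
  meanR2 <- function(seedOff, sched) {
    vapply(1:8, function(r) {
      arch <- sampleGenomeArchitecture(cfg, seed = 600 + r)
      h <- simulateHistorical(arch$map, cfg, sched,
                              seed = seedOff + r)
      lo <- lociInfo(h)
      mr <- which(lo$type == "marker")
      hap <- t(matrix(as.integer(haplotypes(h)[mr, ]), length(mr)))
      meanR2AtDistance(hap, lo[mr, ], targetC = 0.1,
                       window = 0.5)$mean_r2
    }, 0)
  }
  const <- meanR2(100, data.frame(gen = c(0, 40), census = c(200, 200)))
  bott <- meanR2(100, data.frame(gen = c(0, 20, 30, 40),
                                 census = c(200, 200, 25, 200)))
  expect_gt(mean(bott), mean(const))
})

test_that("same seed gives bit-identical populations", {
  th1 <- tinyHistorical(31)
  th2 <- tinyHistorical(31)
  expect_identical(th1$pop@haplo, th2$pop@haplo)
  b1 <- tinyBreed(77, ebvGens = 2, phenGens = 1)
  b2 <- tinyBreed(77, ebvGens = 2, phenGens = 1)
  expect_identical(pedigree(b1$pop), pedigree(b2$pop))
  expect_identical(b1$pop@haplo, b2$pop@haplo)
  expect_identical(phenotypes(b1$pop), phenotypes(b2$pop))
})

test_that("breed founding samples without replacement and preserves
          allele frequencies within sampling error", {
  th <- tinyHistorical(23)
  expect_error(foundBreed(th$pop, nrow(pedigree(th$pop)) + 1),
               "exceeds")
  all <- foundBreed(th$pop, nrow(pedigree(th$pop)), seed = 1)
  expect_equal(sort(colSums(matrix(as.integer(all@haplo), nrow(all@haplo)))),
               sort(colSums(matrix(as.integer(th$pop@haplo),
                                   nrow(th$pop@haplo)))))
  lo <- lociInfo(th$pop)
  mr <- which(lo$type == "marker")
  pHist <- hapstep:::.alleleFreq(th$pop@haplo, mr)
  for (nf in c(30, 120)) {
    b <- foundBreed(th$pop, nf, seed = 2)
    pB <- hapstep:::.alleleFreq(b@haplo, mr)
    se <- sqrt(pHist * (1 - pHist) / (2 * nf))
    # without-replacement sampling is tighter than the binomial SE
    expect_lt(mean(abs(pB - pHist) > 4 * se + 1e-9), 0.02)
  }
  # different seeds give different founder sets
  b1 <- foundBreed(th$pop, 30, seed = 5)
  b2 <- foundBreed(th$pop, 30, seed = 6)
  expect_false(identical(b1@haplo, b2@haplo))
})

test_that("meiosis is Mendelian with Poisson (Haldane) crossovers", {
  cfg <- genomeConfig(data.frame(chrom = 1, length_cM = 120),
                      nMarkersHD = 100, nMarkersMedium = 10, nQTL = 1,
                      nMarkerCandidates = 100, nQTLCandidates = 1)
  arch <- sampleGenomeArchitecture(cfg, seed = 9)
  map <- arch$map
  # one parent heterozygous at every locus: haplotype 1 all 0, 2 all 1;
  # switches along a gamete count crossovers directly
  nl <- nrow(map@loci)
  hap <- matrix(as.raw(0), nl, 2)
  hap[, 2] <- as.raw(1)
  hap[map@loci$type == "qtl", ] <- as.raw(1)  # keep QTL codes valid
  ped <- data.frame(id = 1L, sire = 0L, dam = 0L, sex = 1L,
                    generation = 0L, breed = "x", phase = "founder",
                    pgen = 0L)
  pop <- new("Population", ped = ped, map = map, haplo = hap,
             haploIds = 1L, tbv = NA_real_, polygenic = NA_real_,
             phenotype = NA_real_)
  set.seed(1234)
  n <- 4000
  gam <- hapstep:::.makeGametes(pop, rep(1L, n %/% 2), rep(1L, n %/% 2))
  mr <- which(map@loci$type == "marker")
  G <- matrix(as.integer(gam[mr, ]), length(mr))
  # Mendelian transmission: each locus inherits allele 1 w.p. 0.5
  counts <- rowSums(G)
  chi <- sum((counts - n / 2)^2 / (n / 4))
  expect_lt(chi, qchisq(0.99, df = length(mr)))
  # crossover count between first and last marker ~ Poisson(d/100)
  switches <- colSums(abs(G[-1, ] - G[-nrow(G), ]))
  d <- diff(range(map@loci$pos_cM[mr]))
  expect_lt(abs(mean(switches) - d / 100), 3 * sd(switches) / sqrt(n))
})

test_that("selection moves the mean breeding value in the chosen
          direction", {
  th <- tinyHistorical(41)
  mc <- matingConfig(maxDams = 30)
  shift <- vapply(1:12, function(r) {
    b <- foundBreed(th$pop, 50, seed = 100 + r)
    b <- runRecentSelection(b, 3, mode = "phenotypic", direction = "up",
                            mating = mc, trait = th$trait,
                            seed = 200 + r)
    ped <- pedigree(b)
    mean(tbv(b)[ped$pgen == 3 & ped$phase == "phenotypic"]) -
      mean(tbv(b)[ped$phase == "founder"])
  }, 0)
  # sign test: response should be positive in nearly all replicates
  expect_gte(sum(shift > 0), 10)
  # mirrored direction decreases the mean
  b <- foundBreed(th$pop, 50, seed = 999)
  b <- runRecentSelection(b, 3, mode = "phenotypic", direction = "down",
                          mating = mc, trait = th$trait, seed = 998)
  ped <- pedigree(b)
  expect_lt(mean(tbv(b)[ped$pgen == 3 & ped$phase == "phenotypic"]),
            mean(tbv(b)[ped$phase == "founder"]))
})

test_that("litter sizes follow the configured 30/50/20 odds", {
  set.seed(5)
  draws <- sample.int(3, 1e5, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  f <- tabulate(draws) / 1e5
  expect_equal(f, c(0.3, 0.5, 0.2), tolerance = 0.02)
  # and the simulator's realised litter distribution matches
  b <- tinyBreed(55, ebvGens = 0, phenGens = 4)$pop
  ped <- pedigree(b)
  off <- ped[ped$phase == "phenotypic", ]
  litters <- table(table(paste(off$dam, off$pgen)))
  expect_true(all(names(litters) %in% c("1", "2", "3")))
})

test_that("phenotypes decompose as mu + tbv + residual", {
  th <- tinyHistorical(61, h2 = 0.30)
  # h2 = 1: phenotype equals tbv exactly
  tr1 <- th$trait
  tr1@h2 <- 1; tr1@qtlH2 <- 0.15
  b <- foundBreed(th$pop, 40, seed = 1)
  b <- assignPhenotypes(b, tr1, seed = 2)
  expect_equal(phenotypes(b), tbv(b))
  # founder cohort at large n realises the configured h2
  cfg <- tinyConfig(nHD = 60, nMed = 20, nQTL = 10)
  th2 <- tinyHistorical(62, cfg = cfg, census = 400, gens = 8)
  big <- foundBreed(th2$pop, 400, seed = 3)
  big <- assignPhenotypes(big, th2$trait, seed = 4)
  h2hat <- var(tbv(big)) / var(phenotypes(big))
  expect_lt(abs(h2hat - 0.30), 0.08)
})

test_that("Mendelian deviation shrinks with parental inbreeding", {
  # with fully inbred parents the deviation variance term vanishes
  th <- tinyHistorical(71)
  tr <- th$trait
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  Fp <- pedigreeInbreeding(ped)
  expect_equal(unname(Fp), c(0, 0, 0))
  v1 <- 0.5 * tr@varPolygenic * (1 - 0)
  v2 <- 0.5 * tr@varPolygenic * (1 - 1)
  expect_equal(v2, 0)
  expect_equal(v1, 0.5 * tr@varPolygenic)
})

test_that("composites realise the requested founder proportions and
          admixture frequencies", {
  th <- tinyHistorical(81)
  mc <- matingConfig(maxDams = 40)
  mkb <- function(seed) {
    b <- foundBreed(th$pop, 60, paste0("P", seed), seed = seed)
    runRecentSelection(b, 2, mode = "phenotypic", mating = mc,
                       trait = th$trait, seed = seed + 1)
  }
  p1 <- mkb(301); p2 <- mkb(401)
  comp <- makeComposite(list(p1, p2), c(0.625, 0.375), 80, "C2",
                        nRandomGens = 0, mating = mc, trait = th$trait,
                        seed = 7)
  ped <- pedigree(comp)
  tab <- table(ped$breed[ped$phase == "founder"])
  expect_equal(unname(tab[["P301"]]), 50)
  expect_equal(unname(tab[["P401"]]), 30)
  # founder allele frequencies ~ proportion-weighted parental frequencies
  lo <- lociInfo(comp)
  mr <- which(lo$type == "marker")
  fr <- function(p, ids) {
    cols1 <- hapstep:::hapColOf(p, ids)
    cols <- as.vector(rbind(cols1, cols1 + 1L))
    rowMeans(matrix(as.integer(p@haplo[mr, cols]), length(mr)))
  }
  lastIds <- function(p) {
    pd <- pedigree(p)
    pd$id[pd$generation == max(pd$generation)]
  }
  fC <- hapstep:::.alleleFreq(comp@haplo, mr)
  fMix <- 0.625 * fr(p1, lastIds(p1)) + 0.375 * fr(p2, lastIds(p2))
  expect_lt(mean(abs(fC - fMix)), 0.05)
  # single-parent composite is a plain continuation of that breed
  c1 <- makeComposite(list(p1), 1.0, 60, "C1", nRandomGens = 0,
                      mating = mc, trait = th$trait, seed = 8)
  expect_equal(nrow(pedigree(c1)), 60)
  expect_error(makeComposite(list(p1, p2), c(0.7, 0.2), 50),
               "sum to 1")
})

test_that("genotyping applies the configured missing and error rates", {
  b <- tinyBreed(91, ebvGens = 0, phenGens = 2)$pop
  g0 <- applyGenotyping(b, panel = "medium", missingRate = 0,
                        errorRate = 0)
  lo <- lociInfo(b)
  rows <- which(lo$medium)
  truth <- hapstep:::cpp_dosage(b@haplo, hapstep:::hapColOf(b, b@haploIds),
                                rows)
  expect_equal(unname(dosages(g0)), unname(truth * 1.0))
  g <- applyGenotyping(b, panel = "medium", missingRate = 0.05,
                       errorRate = 0.01, seed = 3)
  d <- dosages(g)
  nCalls <- length(d)
  expect_lt(abs(mean(is.na(d)) - 0.05),
            4 * sqrt(0.05 * 0.95 / nCalls))
  diff <- d != truth
  expect_lt(abs(mean(diff[!is.na(diff)]) - 0.01),
            4 * sqrt(0.01 * 0.99 / (0.95 * nCalls)))
  # an error on a monomorphic locus makes it polymorphic
  one <- matrix(2, 4, 1)
  set.seed(1)
  pert <- (one + sample.int(2, 4, replace = TRUE)) %% 3
  expect_true(any(pert != 2))
})

test_that("variant QC enforces the MAF and heterozygosity rules", {
  mk <- function(d) new("GenotypeData", dosages = d, ids = seq_len(nrow(d)),
                        loci = data.frame(chrom = 1,
                                          pos_cM = seq_len(ncol(d)),
                                          pos_bp = seq_len(ncol(d)),
                                          id = paste0("m", seq_len(ncol(d)))),
                        panel = "medium")
  n <- 100
  set.seed(8)
  good <- function() rbinom(n, 2, 0.4)
  rare <- c(rep(0, n - 1), 1)                    # MAF 0.005 -> out
  allHet <- rep(1, n)                            # het dev 0.5  -> out
  noHet <- rep(c(0, 2), n / 2)                   # p=0.5, het 0 -> out
  d <- cbind(good(), good(), rare, good(), allHet, good(), noHet,
             good(), good(), good())
  q <- qcVariants(mk(d), mafMin = 0.01, hetDevMax = 0.15)
  expect_equal(ncol(dosages(q)), 7)
  expect_equal(attr(q, "qc")$n_removed_maf, 1)
  expect_gte(attr(q, "qc")$n_removed_het, 2)
  # empty result is allowed but flagged
  expect_warning(q2 <- qcVariants(mk(cbind(rare, allHet))), "every locus")
  expect_true(attr(q2, "qc")$empty)
})
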