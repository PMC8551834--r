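# Shared fixtures and independent oracles, all generated in code.

# small genome + historical population, reused by several tests
tinyConfig <- function(nHD = 240, nMed = 120, nQTL = 20,
                       chroms = c(80, 80)) {
  genomeConfig(chroms, nMarkersHD = nHD, nMarkersMedium = nMed,
               nQTL = nQTL, nMarkerCandidates = ceiling(1.3 * nHD),
               nQTLCandidates = nQTL + 10)
}

tinyHistorical <- function(seed, cfg = tinyConfig(), census = 150,
                           gens = 25, h2 = 0.30, qtlH2 = 0.15) {
  arch <- sampleGenomeArchitecture(cfg, h2 = h2, qtlH2 = qtlH2,
                                   seed = seed)
  hist <- simulateHistorical(arch$map, cfg,
                             data.frame(gen = c(0, gens),
                                        census = c(census, census)),
                             seed = seed + 1)
  sel <- selectPanels(hist, cfg, arch$trait, seed = seed + 2)
  trait <- calibrateTrait(sel$trait, sel$pop)
  list(pop = sel$pop, trait = trait, cfg = cfg)
}

# a small breed with phenotypic + EBV phases, for ssGBLUP-level tests
tinyBreed <- function(seed, ebvGens = 4, phenGens = 2, maxDams = 40,
                      h2 = 0.30) {
  th <- tinyHistorical(seed, h2 = h2)
  mc <- matingConfig(maxDams = maxDams)
  b <- foundBreed(th$pop, 60, "tiny", seed = seed + 3)
  b <- runRecentSelection(b, phenGens, mode = "phenotypic", mating = mc,
                          trait = th$trait, seed = seed + 4)
  b <- runRecentSelection(b, ebvGens, mode = "ebv", mating = mc,
                          trait = th$trait, seed = seed + 5)
  list(pop = b, trait = th$trait)
}

# desk-size preset for scenario plumbing tests (10 EBV generations so the
# published generation structure applies)
tinyPreset <- function() {
  p <- presetReduced()
  p$genome <- tinyConfig()
  p$historicalSchedule <- data.frame(gen = c(0, 25), census = c(150, 150))
  p$breeds$Breed_B <- list(founders = 60, phenGens = 2, growth = 0.10,
                           direction = "up")
  p$mating$maxDams <- 40
  p$split <- list(nPhenoTrain = 350, trainPhenoGenerations = 1:8,
                  nGenoTrain = 120, genoTrainGenerations = 4:7,
                  nValidation = 50, validationGenerations = 9:10,
                  gapGeneration = 8)
  p$windowSnps <- 40
  # the tiny fixture carries little genomic information per animal, so
  # the G/A22 compatibility gate is relaxed for these smoke tests
  p$minGACor <- 0.10
  p
}

# --- independent oracles ---------------------------------------------------

# r2 from the 2x2 haplotype table (counts of haplotypes AB, Ab, aB, ab)
r2FromTable <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n
  pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# r2 between two phased 0/1 allele vectors via the haplotype table
r2BruteForce <- function(h1, h2) {
  r2FromTable(sum(h1 == 1 & h2 == 1), sum(h1 == 1 & h2 == 0),
              sum(h1 == 0 & h2 == 1), sum(h1 == 0 & h2 == 0))
}

# exhaustive-blocking oracle: enumerate every set of non-overlapping valid
# intervals on a small map, maximise covered SNPs, tie-break by earliest
# start then longest first interval (recursively)
blockBruteForce <- function(r2mat, thr, window = ncol(r2mat)) {
  m <- nrow(r2mat)
  valid <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):min(m, i + window - 1)) {
    sub <- r2mat[i:j, i:j, drop = FALSE]
    pair <- sub[upper.tri(sub)]
    linked <- vapply(seq_len(j - i + 1), function(k)
      max(sub[k, -k]) >= thr, TRUE)
    if (mean(pair) >= thr && all(linked))
      valid[[length(valid) + 1]] <- c(i, j)
  }
  if (!length(valid)) return(matrix(integer(0), 0, 2))
  iv <- do.call(rbind, valid)
  iv <- iv[order(iv[, 1], -iv[, 2]), , drop = FALSE]
  best <- NULL; bestW <- -1
  better <- function(a, b) {
    # a, b: matrices of intervals sorted by start; TRUE if a preferred
    for (r in seq_len(min(nrow(a), nrow(b)))) {
      if (a[r, 1] != b[r, 1]) return(a[r, 1] < b[r, 1])
      if (a[r, 2] != b[r, 2]) return(a[r, 2] > b[r, 2])
    }
    nrow(a) < nrow(b)
  }
  consider <- function(mat) {
    w <- if (nrow(mat)) sum(mat[, 2] - mat[, 1] + 1) else 0
    if (w > bestW || (w == bestW && !is.null(best) && better(mat, best))) {
      best <<- mat; bestW <<- w
    }
  }
  # enumerate every non-overlapping set once: pick the leftmost interval,
  # recurse on intervals starting after its end
  recurse <- function(minStart, chosen) {
    consider(chosen)
    for (k in seq_len(nrow(iv))) {
      if (iv[k, 1] < minStart) next
      recurse(iv[k, 2] + 1, rbind(chosen, iv[k, ]))
    }
  }
  recurse(1, matrix(integer(0), 0, 2))
  best
}
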