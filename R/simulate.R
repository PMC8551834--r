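# Forward-in-time simulation: historical population, breed founding,
# phenotypic / EBV-based selection, composite breeds, phenotyping.

.chromIndex <- function(map) {
  lo <- map@loci
  ch <- map@chromosomes
  start <- match(ch$chrom, lo$chrom)
  end <- nrow(lo) - match(ch$chrom, rev(lo$chrom)) + 1L
  list(start = as.integer(start), end = as.integer(end),
       len = as.numeric(ch$length_cM), pos = as.numeric(lo$pos_cM))
}

# gametes for a batch of offspring: parentCols alternates sire/dam first
# haplotype columns so the returned columns are offspring-major pairs
.makeGametes <- function(pop, sireIds, damIds, mutate = FALSE, cfg = NULL) {
  ci <- .chromIndex(pop@map)
  sc <- hapColOf(pop, sireIds)
  dc <- hapColOf(pop, damIds)
  cols <- as.integer(as.vector(rbind(sc, dc)))
  gam <- cpp_make_gametes(pop@haplo, cols, ci$pos, ci$start, ci$end, ci$len)
  if (mutate && !is.null(cfg)) {
    lo <- pop@map@loci
    mrows <- which(lo$type == "marker")
    qrows <- which(lo$type == "qtl")
    cpp_mutate_gametes(gam, mrows, cfg@markerMutationRate,
                       lo$n_alleles[mrows], redraw = FALSE)
    cpp_mutate_gametes(gam, qrows, cfg@qtlMutationRate,
                       lo$n_alleles[qrows], redraw = TRUE)
  }
  gam
}

#' Simulate the historical (pre-breed) population
#'
#' Random union of gametes each generation: every offspring draws a random
#' sire from the males and a random dam from the females of the previous
#' generation. The census follows \code{schedule} (linear interpolation
#' between the breakpoints), which is how a bottleneck and recovery are
#' expressed. Recurrent mutation is applied to gametes during this phase
#' only. Sexes alternate deterministically so the sex ratio stays at 1:1.
#'
#' Only the final generation is returned (with phased haplotypes); the
#' historical pedigree is not retained.
#'
#' @param map a \linkS4class{GenomeMap} (candidate loci).
#' @param cfg the \linkS4class{GenomeConfig} (mutation rates).
#' @param schedule data.frame with columns \code{gen} (starting at 0) and
#'   \code{census}; census at intermediate generations is interpolated.
#' @param seed optional seed.
#' @return A \linkS4class{Population} holding the final historical
#'   generation (phase \code{"historical"}).
#' @export
simulateHistorical <- function(map, cfg, schedule, seed = NULL) {
  stopifnot(is.data.frame(schedule), all(c("gen", "census") %in%
                                           names(schedule)))
  if (schedule$gen[1] != 0) stop("schedule must start at generation 0")
  .withSeed(seed, {
    gens <- max(schedule$gen)
    censusAt <- function(g)
      as.integer(round(approx(schedule$gen, schedule$census, g,
                              rule = 2)$y))
    N <- censusAt(0)
    if (N < 2) stop("historical population extinct at generation 0")
    nl <- nrow(map@loci)
    # init: markers at frequency 0.5, QTLs at equal allele frequencies
    hap <- matrix(as.raw(0), nl, 2L * N)
    mrows <- which(map@loci$type == "marker")
    qrows <- which(map@loci$type == "qtl")
    hap[mrows, ] <- as.raw(rbinom(length(mrows) * 2L * N, 1L, 0.5))
    if (length(qrows)) {
      ka <- map@loci$n_alleles[qrows]
      hap[qrows, ] <- as.raw(
        floor(runif(length(qrows) * 2L * N) * rep(ka, 2L * N)) + 1L)
    }
    sex <- rep_len(c(1L, 2L), N)
    pop <- NULL
    for (g in seq_len(gens)) {
      Ng <- censusAt(g)
      if (Ng < 2)
        stop("historical population went extinct at generation ", g,
             " (census ", Ng, ")")
      males <- which(sex == 1L)
      females <- which(sex == 2L)
      if (!length(males) || !length(females))
        stop("historical generation ", g, " lacks one sex")
      sireIdx <- males[sample.int(length(males), Ng, replace = TRUE)]
      damIdx <- females[sample.int(length(females), Ng, replace = TRUE)]
      tmp <- .histPop(map, hap)
      gam <- .makeGametes(tmp, sireIdx, damIdx, mutate = TRUE, cfg = cfg)
      hap <- gam
      sex <- rep_len(c(1L, 2L), Ng)
    }
    .histPop(map, hap, sex = sex)
  })
}

.histPop <- function(map, hap, sex = NULL) {
  N <- ncol(hap) %/% 2L
  ped <- data.frame(id = seq_len(N), sire = 0L, dam = 0L,
                    sex = if (is.null(sex)) rep_len(c(1L, 2L), N) else sex,
                    generation = 0L, breed = "historical",
                    phase = "historical", pgen = 0L)
  new("Population", ped = ped, map = map, haplo = hap,
      haploIds = seq_len(N), tbv = rep(NA_real_, N),
      polygenic = rep(NA_real_, N), phenotype = rep(NA_real_, N))
}

#' Sample the marker panels and final QTL set from segregating loci
#'
#' HD markers are sampled per chromosome (proportional to length) among
#' candidate markers with MAF >= \code{mafMin} in the supplied population;
#' the medium panel is then sampled within each chromosome from the HD
#' panel. QTLs are sampled among candidate QTLs still segregating (major
#' allele frequency <= 1 - \code{mafMin}). Loci not selected are dropped
#' from the map and haplotypes; the trait (if given) is subset accordingly.
#'
#' @param pop the final historical \linkS4class{Population}.
#' @param cfg the \linkS4class{GenomeConfig}.
#' @param trait optional \linkS4class{TraitArchitecture} whose candidate
#'   QTL effects are subset along with the map.
#' @param mafMin segregation threshold for panel sampling (default 0.05).
#' @param seed optional seed.
#' @return list(pop, trait) with the reduced map.
#' @export
selectPanels <- function(pop, cfg, trait = NULL, mafMin = 0.05,
                         seed = NULL) {
  .withSeed(seed, {
    lo <- pop@map@loci
    mrows <- which(lo$type == "marker")
    qrows <- which(lo$type == "qtl")
    pm <- .alleleFreq(pop@haplo, mrows)
    eligibleM <- mrows[pmin(pm, 1 - pm) >= mafMin]
    ch <- pop@map@chromosomes
    nHD <- .allocateByLength(cfg@nMarkersHD, ch$length_cM)
    nMed <- .allocateByLength(cfg@nMarkersMedium, ch$length_cM)
    hdRows <- integer(0)
    medRows <- integer(0)
    for (k in seq_len(nrow(ch))) {
      cand <- eligibleM[lo$chrom[eligibleM] == ch$chrom[k]]
      if (length(cand) < nHD[k])
        stop("chromosome ", ch$chrom[k], ": only ", length(cand),
             " segregating candidate markers for an HD quota of ", nHD[k])
      sel <- sort(sample(cand, nHD[k]))
      hdRows <- c(hdRows, sel)
      medRows <- c(medRows, sort(sample(sel, nMed[k])))
    }
    # QTLs: keep those with at least two alleles segregating
    if (length(qrows)) {
      maxf <- vapply(qrows, function(r) {
        tab <- tabulate(as.integer(pop@haplo[r, ]), nbins = lo$n_alleles[r])
        max(tab) / sum(tab)
      }, 0)
      eligibleQ <- qrows[maxf <= 1 - mafMin]
    } else eligibleQ <- integer(0)
    if (length(eligibleQ) < cfg@nQTL)
      stop("only ", length(eligibleQ), " segregating candidate QTLs for a ",
           "quota of ", cfg@nQTL)
    qtlRows <- sort(sample(eligibleQ, cfg@nQTL))
    keep <- sort(c(hdRows, qtlRows))
    lo2 <- lo[keep, , drop = FALSE]
    lo2$hd <- lo2$type == "marker"
    lo2$medium <- keep %in% medRows
    rownames(lo2) <- NULL
    map2 <- new("GenomeMap", chromosomes = ch, loci = lo2,
                cMPerMb = pop@map@cMPerMb)
    pop@map <- map2
    pop@haplo <- pop@haplo[keep, , drop = FALSE]
    if (!is.null(trait)) {
      sel <- match(qtlRows, trait@qtlIndex)
      if (anyNA(sel)) stop("trait QTL index does not match the map")
      trait@effects <- trait@effects[sel]
      trait@qtlIndex <- which(lo2$type == "qtl")
    }
    validObject(pop)
    list(pop = pop, trait = trait)
  })
}

.alleleFreq <- function(hap, rows) {
  if (!length(rows)) return(numeric(0))
  rowMeans(matrix(as.integer(hap[rows, , drop = FALSE]), length(rows)))
}

#' Found a breed from the historical population
#'
#' Founders are sampled without replacement and become the (unrelated,
#' non-inbred) pedigree base of the breed.
#'
#' @param hist historical \linkS4class{Population}.
#' @param nFounders number of founders (must not exceed the census).
#' @param breed breed label.
#' @param seed optional seed.
#' @return A founder \linkS4class{Population} (generation 0, phase
#'   \code{"founder"}).
#' @export
foundBreed <- function(hist, nFounders, breed = "breed", seed = NULL) {
  .withSeed(seed, {
    N <- nrow(hist@ped)
    if (nFounders > N)
      stop("nFounders (", nFounders, ") exceeds the historical census (",
           N, ")")
    ids <- sort(sample.int(N, nFounders))
    cols1 <- hapColOf(hist, ids)
    cols <- as.vector(rbind(cols1, cols1 + 1L))
    ped <- data.frame(id = seq_len(nFounders), sire = 0L, dam = 0L,
                      sex = hist@ped$sex[ids], generation = 0L,
                      breed = breed, phase = "founder", pgen = 0L)
    new("Population", ped = ped, map = hist@map,
        haplo = hist@haplo[, cols, drop = FALSE],
        haploIds = seq_len(nFounders), tbv = hist@tbv[ids],
        polygenic = hist@polygenic[ids], phenotype = rep(NA_real_,
                                                         nFounders))
  })
}

#' Mating-design configuration for the recent (breed) phases
#'
#' @param sireDamRatio dams per sire (default 25).
#' @param replaceSires,replaceDams per-generation replacement rates of the
#'   breeding males and females (defaults 0.40 and 0.20).
#' @param litterOdds probabilities of single, double and triple births
#'   (defaults 0.30/0.50/0.20).
#' @param femaleGrowth per-generation growth rate of the number of breeding
#'   females (0.10 or 0.15 in the study designs).
#' @param maxDams cap on the number of breeding females.
#' @param minCensus per-generation minimum census assertion (0 disables).
#' @return list of class \code{matingConfig}.
#' @export
matingConfig <- function(sireDamRatio = 25, replaceSires = 0.40,
                         replaceDams = 0.20,
                         litterOdds = c(0.30, 0.50, 0.20),
                         femaleGrowth = 0.10, maxDams = Inf,
                         minCensus = 0) {
  stopifnot(length(litterOdds) == 3, abs(sum(litterOdds) - 1) < 1e-8)
  structure(list(sireDamRatio = sireDamRatio, replaceSires = replaceSires,
                 replaceDams = replaceDams, litterOdds = litterOdds,
                 femaleGrowth = femaleGrowth, maxDams = maxDams,
                 minCensus = minCensus), class = "matingConfig")
}

#' Assign polygenic values, true breeding values and phenotypes
#'
#' Pedigree-base animals draw their polygenic value from
#' N(0, varPolygenic); offspring get the parent average plus a Mendelian
#' deviation with variance \code{0.5 * varPolygenic * (1 - mean(F_parents))}
#' (inbreeding from the pedigree). The true breeding value is the QTL sum
#' plus the polygenic value, and the phenotype is
#' \code{mu + tbv + N(0, varPheno * (1 - h2))}.
#'
#' Only rows with missing values are filled unless \code{overwrite = TRUE}.
#'
#' @param pop a \linkS4class{Population} with stored haplotypes for the
#'   animals to phenotype.
#' @param trait a scaled \linkS4class{TraitArchitecture}.
#' @param overwrite recompute even where values exist.
#' @param seed optional seed.
#' @return The updated population.
#' @export
assignPhenotypes <- function(pop, trait, overwrite = FALSE, seed = NULL) {
  if (!trait@scaled && trait@qtlH2 > 0)
    stop("trait must be calibrated first (calibrateTrait)")
  .withSeed(seed, {
    ped <- pop@ped
    n <- nrow(ped)
    Fped <- cpp_inbreeding(ped$sire, ped$dam)
    todoP <- if (overwrite) rep(TRUE, n) else is.na(pop@polygenic)
    if (any(todoP)) {
      varPoly <- trait@varPolygenic
      for (i in which(todoP)) {
        s <- ped$sire[i]; d <- ped$dam[i]
        if (s == 0L && d == 0L) {
          pop@polygenic[i] <- rnorm(1, 0, sqrt(varPoly))
        } else {
          pa <- mean(c(if (s > 0) pop@polygenic[s],
                       if (d > 0) pop@polygenic[d]))
          Fbar <- mean(c(if (s > 0) Fped[s] else 0,
                         if (d > 0) Fped[d] else 0))
          pop@polygenic[i] <- pa +
            rnorm(1, 0, sqrt(0.5 * varPoly * (1 - Fbar)))
        }
      }
    }
    todoT <- if (overwrite) rep(TRUE, n) else is.na(pop@tbv)
    if (any(todoT)) {
      ids <- ped$id[todoT]
      pop@tbv[todoT] <- .qtlBV(pop, trait, ids) + pop@polygenic[todoT]
    }
    todoY <- if (overwrite) rep(TRUE, n) else is.na(pop@phenotype)
    if (any(todoY)) {
      varE <- trait@varPheno * (1 - trait@h2)
      pop@phenotype[todoY] <- trait@mu + pop@tbv[todoY] +
        if (varE > 0) rnorm(sum(todoY), 0, sqrt(varE)) else 0
    }
    pop
  })
}

# pedigree BLUP (animal model, generation fixed effect) used for EBV-based
# selection; solves the sparse MME directly
.pedigreeBLUP <- function(ped, phen, varA, varE) {
  rec <- which(!is.na(phen))
  n <- nrow(ped)
  gen <- factor(ped$generation[rec])
  X <- Matrix::sparse.model.matrix(~gen)
  Z <- Matrix::sparseMatrix(i = seq_along(rec), j = rec,
                            x = 1, dims = c(length(rec), n))
  Ainv <- aInverse(ped)
  lambda <- varE / varA
  W <- cbind(X, Z)
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) +
    Matrix::bdiag(Matrix::Diagonal(ncol(X), 0), lambda * Ainv))
  rhs <- Matrix::crossprod(W, phen[rec])
  sol <- as.numeric(Matrix::solve(Cholesky(C, LDL = FALSE), rhs))
  sol[ncol(X) + seq_len(n)]
}

#' Run generations of selection (phenotypic, EBV-based or random mating)
#'
#' Each generation, every breeding female produces one litter of 1-3
#' offspring (odds from \code{mating$litterOdds}) by a randomly assigned
#' breeding male. Offspring are phenotyped at birth. Candidates are ranked
#' by phenotype (\code{mode = "phenotypic"}), by pedigree-BLUP EBV solved on
#' all records to date with the true variance components
#' (\code{mode = "ebv"}), or randomly (\code{mode = "random"});
#' \code{direction = "down"} ranks ascending. The configured fractions of
#' sires and dams are replaced by top-ranked candidates each generation and
#' the female herd grows at \code{mating$femaleGrowth} up to
#' \code{mating$maxDams}. Ties are broken by a seeded random shuffle.
#'
#' @param pop a \linkS4class{Population} (founders or a previous phase).
#' @param nGens number of generations to simulate.
#' @param mode selection criterion.
#' @param direction \code{"up"} or \code{"down"}.
#' @param mating a \code{\link{matingConfig}}.
#' @param trait a scaled \linkS4class{TraitArchitecture} (phenotypes are
#'   always assigned).
#' @param phase label recorded in the pedigree \code{phase} column
#'   (defaults to \code{mode}).
#' @param seed optional seed.
#' @return The extended population.
#' @export
runRecentSelection <- function(pop, nGens, mode = c("ebv", "phenotypic",
                                                    "random"),
                               direction = c("up", "down"),
                               mating = matingConfig(), trait,
                               phase = NULL, seed = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (is.null(phase)) phase <- mode
  .withSeed(seed, {
    pop <- assignPhenotypes(pop, trait)
    ped <- pop@ped
    curGen <- max(ped$generation)
    cur <- ped$id[ped$generation == curGen]
    females <- cur[ped$sex[cur] == 2L]
    males <- cur[ped$sex[cur] == 1L]
    if (!length(females) || !length(males))
      stop("current generation lacks breeding animals of one sex")
    nDams <- min(length(females), mating$maxDams)
    dams <- if (nDams < length(females)) sample(females, nDams) else females
    nSires <- max(2L, ceiling(nDams / mating$sireDamRatio))
    sires <- if (nSires < length(males)) sample(males, nSires) else males
    breedLab <- ped$breed[match(cur[1], ped$id)]

    rankOf <- function(ids, crit) {
      v <- crit[ids]
      if (direction == "down") v <- -v
      ids[order(v, runif(length(ids)), decreasing = TRUE)]
    }

    for (g in seq_len(nGens)) {
      litter <- sample.int(3L, length(dams), replace = TRUE,
                           prob = mating$litterOdds)
      sireOfDam <- sires[sample.int(length(sires), length(dams),
                                    replace = TRUE)]
      offSire <- rep(sireOfDam, litter)
      offDam <- rep(dams, litter)
      nOff <- length(offSire)
      if (mating$minCensus > 0 && nOff < mating$minCensus)
        stop("generation census ", nOff, " fell below the configured ",
             "minimum of ", mating$minCensus)
      gam <- .makeGametes(pop, offSire, offDam)
      newIds <- nrow(pop@ped) + seq_len(nOff)
      newPed <- data.frame(id = newIds, sire = offSire, dam = offDam,
                           sex = rbinom(nOff, 1L, 0.5) + 1L,
                           generation = curGen + g, breed = breedLab,
                           phase = phase, pgen = g)
      if (all(newPed$sex == 1L)) newPed$sex[1] <- 2L
      if (all(newPed$sex == 2L)) newPed$sex[1] <- 1L
      pop@ped <- rbind(pop@ped, newPed)
      pop@haplo <- cbind(pop@haplo, gam)
      pop@haploIds <- c(pop@haploIds, newIds)
      pop@tbv <- c(pop@tbv, rep(NA_real_, nOff))
      pop@polygenic <- c(pop@polygenic, rep(NA_real_, nOff))
      pop@phenotype <- c(pop@phenotype, rep(NA_real_, nOff))
      pop <- assignPhenotypes(pop, trait)

      crit <- switch(mode,
        phenotypic = pop@phenotype,
        random = runif(nrow(pop@ped)),
        ebv = .pedigreeBLUP(pop@ped, pop@phenotype,
                            varA = trait@h2 * trait@varPheno,
                            varE = (1 - trait@h2) * trait@varPheno))

      candM <- rankOf(newIds[newPed$sex == 1L], crit)
      candF <- rankOf(newIds[newPed$sex == 2L], crit)
      damTarget <- min(mating$maxDams,
                       max(1L, round(nDams * (1 + mating$femaleGrowth))))
      sireTarget <- max(2L, ceiling(damTarget / mating$sireDamRatio))
      nCullS <- min(length(sires), ceiling(mating$replaceSires *
                                             length(sires)))
      nCullD <- min(length(dams), ceiling(mating$replaceDams * length(dams)))
      keepS <- head(rankOf(sires, crit), length(sires) - nCullS)
      keepD <- head(rankOf(dams, crit), length(dams) - nCullD)
      needS <- max(0L, sireTarget - length(keepS))
      needD <- max(0L, damTarget - length(keepD))
      sires <- c(keepS, head(candM, needS))
      dams <- c(keepD, head(candF, needD))
      if (!length(sires))
        stop("no breeding males selected; infeasible mating configuration")
      if (!length(dams))
        stop("no breeding females selected; infeasible mating configuration")
      nDams <- length(dams)
    }
    pop
  })
}

#' Create a composite breed by admixing pure breeds
#'
#' Founders are sampled from the latest generation of each parent breed in
#' the given proportions (largest-remainder rounding) and become a new
#' pedigree base whose \code{breed} column records the source breed; the
#' composite is then mated at random within itself for
#' \code{nRandomGens} generations.
#'
#' @param pops list of parent \linkS4class{Population}s sharing one genome.
#' @param proportions founder contribution per parent breed (sums to 1).
#' @param nFounders total number of composite founders.
#' @param breed composite breed label for the descendants.
#' @param nRandomGens generations of within-composite random mating.
#' @param mating a \code{\link{matingConfig}}.
#' @param trait scaled \linkS4class{TraitArchitecture}.
#' @param seed optional seed.
#' @return The composite \linkS4class{Population}.
#' @export
makeComposite <- function(pops, proportions, nFounders, breed = "composite",
                          nRandomGens = 5, mating = matingConfig(),
                          trait, seed = NULL) {
  stopifnot(length(pops) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  loci0 <- pops[[1]]@map@loci
  for (p in pops[-1])
    if (!identical(p@map@loci$id, loci0$id))
      stop("parent breeds do not share the same genome map")
  .withSeed(seed, {
    nk <- .allocateByLength(nFounders, proportions)
    pedL <- list(); hapL <- list(); tbvL <- list(); pgL <- list()
    nid <- 0L
    for (k in seq_along(pops)) {
      pk <- pops[[k]]
      last <- pk@ped$id[pk@ped$generation == max(pk@ped$generation)]
      if (nk[k] > length(last))
        stop("breed ", k, " has only ", length(last),
             " animals in its latest generation; need ", nk[k])
      ids <- sort(sample(last, nk[k]))
      cols1 <- hapColOf(pk, ids)
      cols <- as.vector(rbind(cols1, cols1 + 1L))
      src <- unique(pk@ped$breed[match(ids, pk@ped$id)])[1]
      pedL[[k]] <- data.frame(id = nid + seq_len(nk[k]), sire = 0L,
                              dam = 0L, sex = pk@ped$sex[match(ids,
                                                               pk@ped$id)],
                              generation = 0L, breed = src,
                              phase = "founder", pgen = 0L)
      hapL[[k]] <- pk@haplo[, cols, drop = FALSE]
      tbvL[[k]] <- pk@tbv[match(ids, pk@ped$id)]
      pgL[[k]] <- pk@polygenic[match(ids, pk@ped$id)]
      nid <- nid + nk[k]
    }
    ped <- do.call(rbind, pedL)
    comp <- new("Population", ped = ped, map = pops[[1]]@map,
                haplo = do.call(cbind, hapL), haploIds = ped$id,
                tbv = unlist(tbvL), polygenic = unlist(pgL),
                phenotype = rep(NA_real_, nrow(ped)))
    if (nRandomGens > 0) {
      comp <- runRecentSelection(comp, nRandomGens, mode = "random",
                                 mating = mating, trait = trait,
                                 phase = "random")
      comp@ped$breed[comp@ped$phase == "random"] <- breed
    }
    comp
  })
}
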