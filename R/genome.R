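# Genome configuration, locus placement and trait architecture.

#' Create a genome configuration
#'
#' @param chromosomes data.frame with columns \code{chrom} and
#'   \code{length_cM}, or a numeric vector of chromosome lengths in cM.
#' @param nMarkersHD,nMarkersMedium sizes of the high-density panel and of
#'   the medium panel nested within it.
#' @param nQTL number of QTLs kept on the genome.
#' @param nMarkerCandidates,nQTLCandidates candidate loci simulated through
#'   the historical phase; panels are sampled from candidates still
#'   segregating (MAF >= 0.05), so candidates must exceed the panel sizes.
#'   Defaults add 25\% headroom.
#' @param markerMutationRate,qtlMutationRate recurrent per-locus per-gamete
#'   mutation rates applied during the historical phase (default 1e-4).
#' @param qtlAlleleRange inclusive range of allele counts per QTL, default
#'   2 to 6.
#' @param cMPerMb genetic-to-physical ratio; 1 cM = 1 Mb by default.
#' @return A \linkS4class{GenomeConfig}.
#' @export
genomeConfig <- function(chromosomes, nMarkersHD, nMarkersMedium, nQTL,
                         nMarkerCandidates = ceiling(1.25 * nMarkersHD),
                         nQTLCandidates = ceiling(1.25 * nQTL),
                         markerMutationRate = 1e-4, qtlMutationRate = 1e-4,
                         qtlAlleleRange = c(2, 6), cMPerMb = 1) {
  if (is.numeric(chromosomes))
    chromosomes <- data.frame(chrom = seq_along(chromosomes),
                              length_cM = as.numeric(chromosomes))
  new("GenomeConfig", chromosomes = chromosomes, cMPerMb = cMPerMb,
      nMarkersHD = nMarkersHD, nMarkersMedium = nMarkersMedium,
      nQTL = nQTL, nMarkerCandidates = nMarkerCandidates,
      nQTLCandidates = nQTLCandidates,
      markerMutationRate = markerMutationRate,
      qtlMutationRate = qtlMutationRate, qtlAlleleRange = qtlAlleleRange)
}

# allocate a total count across chromosomes proportionally to length,
# largest-remainder rounding so the total is exact
.allocateByLength <- function(total, lengths) {
  raw <- total * lengths / sum(lengths)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Place candidate markers and QTLs and draw the trait architecture
#'
#' Marker and QTL candidates are placed uniformly at random on distinct
#' 1-based bp positions within each chromosome (counts proportional to
#' chromosome length), so marker and QTL positions are disjoint by
#' construction. Per-allele QTL effects are drawn from a gamma distribution
#' with shape 0.4 and a random sign; they are rescaled to the target QTL
#' variance later, on a founder population, by \code{\link{calibrateTrait}}.
#'
#' @param cfg a \linkS4class{GenomeConfig}.
#' @param h2 trait heritability (e.g. 0.30 or 0.10).
#' @param qtlH2 part of the phenotypic variance explained by the QTLs
#'   (defaults to half of \code{h2}); the remainder of the genetic variance,
#'   \code{(h2 - qtlH2) * varPheno}, is polygenic.
#' @param varPheno phenotypic variance (default 100).
#' @param mu trait mean.
#' @param gammaShape shape of the QTL effect distribution (default 0.4).
#' @param seed optional seed (the ambient RNG state is restored on exit).
#' @return list with elements \code{map} (a \linkS4class{GenomeMap} of
#'   candidate loci; panel flags are set later by \code{\link{selectPanels}})
#'   and \code{trait} (an unscaled \linkS4class{TraitArchitecture}).
#' @export
sampleGenomeArchitecture <- function(cfg, h2 = 0.30, qtlH2 = h2 / 2,
                                     varPheno = 100, mu = 0,
                                     gammaShape = 0.4, seed = NULL) {
  .withSeed(seed, {
    ch <- cfg@chromosomes
    nM <- .allocateByLength(cfg@nMarkerCandidates, ch$length_cM)
    nQ <- .allocateByLength(cfg@nQTLCandidates, ch$length_cM)
    loci <- vector("list", nrow(ch))
    for (k in seq_len(nrow(ch))) {
      bpLen <- round(ch$length_cM[k] / cfg@cMPerMb * 1e6)
      tot <- nM[k] + nQ[k]
      if (tot > bpLen)
        stop("more loci than distinguishable bp positions on chromosome ",
             ch$chrom[k])
      pos <- sort(sample.int(bpLen, tot))
      type <- rep("marker", tot)
      type[sample.int(tot, nQ[k])] <- "qtl"
      loci[[k]] <- data.frame(chrom = ch$chrom[k], pos_bp = pos,
                              pos_cM = pos / 1e6 * cfg@cMPerMb, type = type)
    }
    loci <- do.call(rbind, loci)
    loci$n_alleles <- 2L
    qtl <- loci$type == "qtl"
    loci$n_alleles[qtl] <- as.integer(sample(
      seq(cfg@qtlAlleleRange[1], cfg@qtlAlleleRange[2]), sum(qtl),
      replace = TRUE))
    loci$hd <- FALSE
    loci$medium <- FALSE
    loci$id <- paste0(ifelse(qtl, "QTL", "M"), "_", loci$chrom, "_",
                      loci$pos_bp)
    loci <- loci[, c("chrom", "pos_cM", "pos_bp", "type", "hd", "medium",
                     "n_alleles", "id")]
    rownames(loci) <- NULL
    map <- new("GenomeMap", chromosomes = ch, loci = loci,
               cMPerMb = cfg@cMPerMb)
    effects <- lapply(which(qtl), function(i) {
      k <- loci$n_alleles[i]
      rgamma(k, shape = gammaShape) * sample(c(-1, 1), k, replace = TRUE)
    })
    trait <- new("TraitArchitecture", h2 = h2, qtlH2 = qtlH2,
                 varPheno = varPheno,
                 varPolygenic = (h2 - qtlH2) * varPheno, mu = mu,
                 effects = effects, qtlIndex = which(qtl), scaled = FALSE)
    list(map = map, trait = trait)
  })
}

# QTL part of the breeding value for the given ids (haplotypes must be
# stored). Returns a numeric vector in the order of `ids`.
.qtlBV <- function(pop, trait, ids) {
  qrows <- trait@qtlIndex
  if (length(qrows) == 0) return(numeric(length(ids)))
  cols1 <- hapColOf(pop, ids)
  cols <- as.vector(rbind(cols1, cols1 + 1L))
  H <- pop@haplo[qrows, cols, drop = FALSE]
  n <- length(ids)
  bv <- numeric(n)
  odd <- seq(1L, 2L * n, by = 2L)
  for (r in seq_along(qrows)) {
    e <- trait@effects[[r]]
    v <- e[as.integer(H[r, ])]
    bv <- bv + v[odd] + v[odd + 1L]
  }
  bv
}

#' Rescale QTL effects to the realised founder variance
#'
#' Computes the QTL part of the breeding values on the supplied founder
#' population, centres each QTL's allele effects, and rescales all effects
#' so that the realised QTL variance equals \code{qtlH2 * varPheno}. After
#' calibration \code{varPolygenic = (h2 - qtlH2) * varPheno} completes the
#' genetic variance.
#'
#' @param trait an unscaled \linkS4class{TraitArchitecture} whose
#'   \code{qtlIndex} refers to rows of \code{pop}'s map.
#' @param pop the founder \linkS4class{Population} (typically the final
#'   historical generation).
#' @return The scaled trait.
#' @export
calibrateTrait <- function(trait, pop) {
  if (trait@qtlH2 == 0 || length(trait@qtlIndex) == 0) {
    trait@effects <- lapply(trait@effects, function(e) e * 0)
    trait@scaled <- TRUE
    return(trait)
  }
  bv <- .qtlBV(pop, trait, pop@haploIds)
  v <- var(bv)
  if (v <= 0)
    stop("no realised QTL variance in the founder population; ",
         "cannot calibrate the trait")
  sc <- sqrt(trait@qtlH2 * trait@varPheno / v)
  trait@effects <- lapply(trait@effects, function(e) (e - mean(e)) * sc)
  trait@scaled <- TRUE
  trait
}

# run expr under a temporary seed; ambient RNG state is restored afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
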