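# Study presets: the reduced (desk-scale) default and the full-scale
# configuration of the original breeding-program design.

# OAR-like ovine autosome proportions rescaled to a 2,656 cM total
.sheepChromLengths <- function() {
  mb <- c(275, 249, 224, 119, 108, 117, 100, 91, 95, 86, 62, 79, 83, 63,
          81, 72, 72, 69, 60, 51, 50, 51, 62, 42, 45, 44)
  round(mb / sum(mb) * 2656)
}

#' Study presets
#'
#' \code{presetReduced()} is the desk-scale default used throughout the
#' package: 5 chromosomes of 100 cM, a 4,000-marker HD panel with a
#' 1,000-marker medium panel nested in it, 300 multi-allelic QTLs, a
#' 125-generation historical population (census 600, bottleneck to 350,
#' recovery to 800), breed founder sizes 150/300/550 (small/medium/large),
#' and recent populations of roughly 150-480 animals per generation
#' (female herd capped at 250 breeding dams). The training/validation
#' split samples 1,500 phenotyped (generations 1-8), 400 genotyped
#' (generations 4-7) and 150 validation animals (generations 9-10),
#' keeping the study generation structure with generation 8 as a
#' genotype gap.
#'
#' \code{presetPaper()} carries the full-scale design (26 autosomes
#' totalling 2,656 cM, 576,595 HD / 46,827 medium markers, 3,057 QTLs,
#' historical census 80,000 with a bottleneck to 50,000 and recovery to
#' 60,000, founder sizes 2,480/12,480/41,600, 60,000/8,000/2,000 split).
#' Running it is a cluster-scale exercise; it is provided as
#' configuration, not as the test default.
#'
#' @return list with components \code{genome} (a
#'   \linkS4class{GenomeConfig}), \code{historicalSchedule},
#'   \code{breeds}, \code{composites}, \code{ebvGens}, \code{mating},
#'   \code{split}, \code{genotyping}, \code{qc}, \code{ldThresholds},
#'   \code{windowSnps}, \code{blend}, \code{minGACor} and \code{solver}.
#' @export
presetReduced <- function() {
  list(
    genome = genomeConfig(rep(100, 5), nMarkersHD = 4000,
                          nMarkersMedium = 1000, nQTL = 300,
                          nMarkerCandidates = 5000, nQTLCandidates = 400),
    historicalSchedule = data.frame(gen = c(0, 100, 115, 125),
                                    census = c(600, 600, 350, 800)),
    breeds = list(
      Breed_A = list(founders = 150, phenGens = 10, growth = 0.10,
                     direction = "up"),
      Breed_B = list(founders = 150, phenGens = 10, growth = 0.10,
                     direction = "up"),
      Breed_C = list(founders = 300, phenGens = 1, growth = 0.15,
                     direction = "up"),
      Breed_D = list(founders = 550, phenGens = 1, growth = 0.15,
                     direction = "up"),
      Breed_E = list(founders = 550, phenGens = 1, growth = 0.15,
                     direction = "down")),
    composites = list(
      Comp_2 = list(parents = c("Breed_D", "Breed_E"),
                    proportions = c(0.625, 0.375), founders = 300,
                    randomGens = 5, direction = "down"),
      Comp_3 = list(parents = c("Breed_A", "Breed_B", "Breed_C"),
                    proportions = c(0.375, 0.375, 0.25), founders = 300,
                    randomGens = 5, direction = "up")),
    ebvGens = 10,
    mating = matingConfig(sireDamRatio = 25, replaceSires = 0.40,
                          replaceDams = 0.20,
                          litterOdds = c(0.30, 0.50, 0.20),
                          femaleGrowth = 0.10, maxDams = 250),
    split = list(nPhenoTrain = 1500, trainPhenoGenerations = 1:8,
                 nGenoTrain = 400, genoTrainGenerations = 4:7,
                 nValidation = 150, validationGenerations = 9:10,
                 gapGeneration = 8),
    genotyping = list(missingRate = 0.05, errorRate = 0.01),
    qc = list(mafMin = 0.01, hetDevMax = 0.15),
    ldThresholds = c(0.1, 0.3, 0.6),
    windowSnps = 100,
    blend = list(alpha = 0.95, beta = 0.05, tau = 1, omega = 1),
    minGACor = 0.30,
    solver = list(pcgTol = 1e-12, pcgMaxIter = 5000,
                  remlMethod = "profile", remlTol = 1e-8)
  )
}

#' @rdname presetReduced
#' @export
presetPaper <- function() {
  p <- presetReduced()
  p$genome <- genomeConfig(.sheepChromLengths(), nMarkersHD = 576595,
                           nMarkersMedium = 46827, nQTL = 3057,
                           nMarkerCandidates = 700000,
                           nQTLCandidates = 4000)
  p$historicalSchedule <- data.frame(gen = c(0, 1000, 1500),
                                     census = c(80000, 50000, 60000))
  p$breeds <- list(
    Breed_A = list(founders = 2480, phenGens = 10, growth = 0.10,
                   direction = "up"),
    Breed_B = list(founders = 2480, phenGens = 10, growth = 0.10,
                   direction = "down"),
    Breed_C = list(founders = 12480, phenGens = 1, growth = 0.15,
                   direction = "up"),
    Breed_D = list(founders = 41600, phenGens = 1, growth = 0.15,
                   direction = "up"),
    Breed_E = list(founders = 41600, phenGens = 1, growth = 0.15,
                   direction = "down"))
  p$composites <- list(
    Comp_2 = list(parents = c("Breed_D", "Breed_E"),
                  proportions = c(0.625, 0.375), founders = 20000,
                  randomGens = 5, direction = "down"),
    Comp_3 = list(parents = c("Breed_A", "Breed_B", "Breed_C"),
                  proportions = c(0.375, 0.375, 0.25), founders = 20000,
                  randomGens = 5, direction = "up"))
  p$mating <- matingConfig(sireDamRatio = 25, replaceSires = 0.40,
                           replaceDams = 0.20,
                           litterOdds = c(0.30, 0.50, 0.20),
                           femaleGrowth = 0.10, maxDams = 5000,
                           minCensus = 7000)
  p$split <- list(nPhenoTrain = 60000, trainPhenoGenerations = 1:8,
                  nGenoTrain = 8000, genoTrainGenerations = 4:7,
                  nValidation = 2000, validationGenerations = 9:10,
                  gapGeneration = 8)
  p
}

#' Simulate one study population end to end
#'
#' Runs the full generative pipeline for one of the five study
#' populations: historical population, panel sampling, trait calibration,
#' breed founding, the breed's phenotypic-selection phase, and (for
#' composites) admixture plus random mating, followed by the EBV-based
#' selection phase whose generations 1-10 are the material for the
#' prediction scenarios.
#'
#' @param population one of \code{"Breed_B"}, \code{"Breed_C"},
#'   \code{"Breed_E"}, \code{"Comp_2"}, \code{"Comp_3"} (pure breeds A and
#'   D are available as parents of the composites).
#' @param h2 trait heritability (0.30 moderate / 0.10 low).
#' @param qtlH2 QTL-explained part (defaults to half of \code{h2} as in
#'   the moderate design; the low design uses 0.01).
#' @param preset a preset list, see \code{\link{presetReduced}}.
#' @param seed seed for the whole replicate.
#' @return list(pop, trait, preset).
#' @export
simulateStudyPopulation <- function(population = "Breed_B", h2 = 0.30,
                                    qtlH2 = h2 / 2,
                                    preset = presetReduced(),
                                    seed = NULL) {
  .withSeed(seed, {
    arch <- sampleGenomeArchitecture(preset$genome, h2 = h2,
                                     qtlH2 = qtlH2)
    hist <- simulateHistorical(arch$map, preset$genome,
                               preset$historicalSchedule)
    sel <- selectPanels(hist, preset$genome, arch$trait)
    hist <- sel$pop
    trait <- calibrateTrait(sel$trait, hist)

    runBreed <- function(name) {
      bd <- preset$breeds[[name]]
      mc <- preset$mating
      mc$femaleGrowth <- bd$growth
      b <- foundBreed(hist, bd$founders, breed = name)
      runRecentSelection(b, bd$phenGens, mode = "phenotypic",
                         direction = "up", mating = mc, trait = trait,
                         phase = "phenotypic")
    }

    if (population %in% names(preset$breeds)) {
      bd <- preset$breeds[[population]]
      mc <- preset$mating
      mc$femaleGrowth <- bd$growth
      pop <- runBreed(population)
      pop <- runRecentSelection(pop, preset$ebvGens, mode = "ebv",
                                direction = bd$direction, mating = mc,
                                trait = trait, phase = "ebv")
    } else if (population %in% names(preset$composites)) {
      cd <- preset$composites[[population]]
      parents <- lapply(cd$parents, runBreed)
      pop <- makeComposite(parents, cd$proportions, cd$founders,
                           breed = population,
                           nRandomGens = cd$randomGens,
                           mating = preset$mating, trait = trait)
      pop <- runRecentSelection(pop, preset$ebvGens, mode = "ebv",
                                direction = cd$direction,
                                mating = preset$mating, trait = trait,
                                phase = "ebv")
    } else {
      stop("unknown population '", population, "'")
    }
    list(pop = pop, trait = trait, preset = preset)
  })
}
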