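# Training/validation design, the scenario grid, GEBV accuracy and bias,
# and the per-replicate scenario runner.

#' Default marker configurations (the eleven scenarios)
#'
#' SNPs from the HD panel; SNPs from the medium panel; independent SNPs +
#' pseudo-SNPs in one G (IPS) at LD thresholds 0.1/0.3/0.6; pseudo-SNPs
#' only (PS) at the three thresholds; and independent + pseudo-SNPs in two
#' relationship matrices (IPS_2H) at the three thresholds.
#'
#' @return data.frame(scenario, variant, threshold).
#' @export
markerConfigs <- function() {
  data.frame(
    scenario = c("SNP_HD", "SNP_MED", "IPS_LD01", "IPS_LD03", "IPS_LD06",
                 "PS_LD01", "PS_LD03", "PS_LD06", "IPS_2H_LD01",
                 "IPS_2H_LD03", "IPS_2H_LD06"),
    variant = c("snp_hd", "snp_medium", rep("ips", 3), rep("ps", 3),
                rep("ips2h", 3)),
    threshold = c(NA, NA, 0.1, 0.3, 0.6, 0.1, 0.3, 0.6, 0.1, 0.3, 0.6))
}

#' Enumerate the scenario grid
#'
#' Full cross product of marker configurations, heritability levels and
#' populations; the study design (11 x 2 x 5) gives 110 descriptors.
#'
#' @param populations character vector of population labels.
#' @param h2Levels numeric heritabilities.
#' @param configs data.frame as returned by \code{\link{markerConfigs}}.
#' @return data.frame of descriptors with a unique \code{id}.
#' @export
scenarioGrid <- function(populations = c("Breed_B", "Breed_C", "Breed_E",
                                         "Comp_2", "Comp_3"),
                         h2Levels = c(0.30, 0.10),
                         configs = markerConfigs()) {
  g <- expand.grid(scenario = configs$scenario, h2 = h2Levels,
                   population = populations, stringsAsFactors = FALSE)
  g <- merge(g, configs, by = "scenario", sort = FALSE)
  g$id <- sprintf("%s_h2%02.0f_%s", g$population, 100 * g$h2, g$scenario)
  stopifnot(!anyDuplicated(g$id))
  g[order(g$population, -g$h2, match(g$scenario, configs$scenario)),
    c("id", "population", "h2", "scenario", "variant", "threshold")]
}

#' GEBV accuracy
#'
#' Pearson correlation between GEBVs and true breeding values in the
#' validation set. Undefined (NA) with fewer than 3 animals or zero
#' variance in either vector.
#'
#' @param gebv,tbv numeric vectors of equal length.
#' @return Correlation, or NA when undefined.
#' @export
gebvAccuracy <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv))
  if (length(gebv) < 3) return(NA_real_)
  if (sd(gebv) == 0 || sd(tbv) == 0) return(NA_real_)
  cor(gebv, tbv)
}

#' GEBV dispersion bias
#'
#' \code{beta1 - 1} from the regression TBV = beta0 + beta1 * GEBV;
#' negative values indicate over-dispersed (inflated) GEBVs.
#'
#' @param gebv,tbv numeric vectors of equal length.
#' @return Slope minus one, or NA when undefined.
#' @export
gebvBias <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv))
  if (length(gebv) < 3 || sd(gebv) == 0) return(NA_real_)
  unname(coef(lm(tbv ~ gebv))[2] - 1)
}

#' Split a simulated population into training and validation sets
#'
#' Random sampling according to the split specification: phenotyped
#' training animals from the early EBV generations, genotyped training
#' animals among them from the middle generations, and genotyped
#' validation animals from the last generations. The gap generation
#' contributes phenotypes but no genotypes; validation animals' phenotypes
#' are masked (they are simply not in the phenotype records handed to the
#' solver). The whole pedigree is always retained.
#'
#' @param pop a \linkS4class{Population} with an \code{"ebv"} phase.
#' @param split list with \code{nPhenoTrain}, \code{trainPhenoGenerations},
#'   \code{nGenoTrain}, \code{genoTrainGenerations}, \code{nValidation},
#'   \code{validationGenerations}, \code{gapGeneration} (see
#'   \code{\link{presetReduced}}).
#' @param seed optional seed.
#' @return list(phenoIds, genoTrainIds, validationIds, records) where
#'   \code{records} is a data.frame(id, generation, y) of unmasked
#'   training phenotypes.
#' @export
splitTrainingValidation <- function(pop, split, seed = NULL) {
  .withSeed(seed, {
    ped <- pop@ped
    ebv <- ped$phase == "ebv"
    pickFrom <- function(gens, n, what) {
      cand <- ped$id[ebv & ped$pgen %in% gens]
      if (length(cand) < n)
        stop("only ", length(cand), " animals available for the ", what,
             " sample of ", n)
      sort(sample(cand, n))
    }
    phenoIds <- pickFrom(split$trainPhenoGenerations, split$nPhenoTrain,
                         "phenotyped training")
    genoPool <- intersect(phenoIds,
                          ped$id[ebv & ped$pgen %in%
                                   split$genoTrainGenerations])
    if (length(genoPool) < split$nGenoTrain)
      stop("only ", length(genoPool), " phenotyped animals in the ",
           "genotyping generations; need ", split$nGenoTrain)
    genoTrainIds <- sort(sample(genoPool, split$nGenoTrain))
    validationIds <- pickFrom(split$validationGenerations,
                              split$nValidation, "validation")
    if (length(intersect(validationIds, phenoIds)))
      stop("validation and training overlap; check the generation ranges")
    if (any(ped$pgen[match(genoTrainIds, ped$id)] ==
              split$gapGeneration))
      stop("gap generation animals must not be genotyped")
    records <- data.frame(id = phenoIds,
                          generation = ped$generation[match(phenoIds,
                                                            ped$id)],
                          y = pop@phenotype[match(phenoIds, ped$id)])
    list(phenoIds = phenoIds, genoTrainIds = genoTrainIds,
         validationIds = validationIds, records = records)
  })
}

# Assemble and cache everything the scenarios of one replicate share:
# genotypes and QC per panel, phased haplotypes of the genotyped set on
# the QC-passed medium panel, pedigree matrices, and the phenotype records.
#' Prepare the shared inputs for the prediction scenarios of one replicate
#'
#' @param pop,trait a simulated population and its trait (see
#'   \code{\link{simulateStudyPopulation}}).
#' @param preset the preset list used to simulate it.
#' @param seed optional seed (genotyping perturbations and the split).
#' @return An environment consumed by \code{\link{runScenario}}.
#' @export
prepareScenarioData <- function(pop, trait, preset, seed = NULL) {
  .withSeed(seed, {
    sp <- splitTrainingValidation(pop, preset$split)
    genoIds <- sort(c(sp$genoTrainIds, sp$validationIds))
    gHD <- applyGenotyping(pop, genoIds, "hd",
                           preset$genotyping$missingRate,
                           preset$genotyping$errorRate)
    gMED <- applyGenotyping(pop, genoIds, "medium",
                            preset$genotyping$missingRate,
                            preset$genotyping$errorRate)
    qHD <- qcVariants(gHD, preset$qc$mafMin, preset$qc$hetDevMax)
    qMED <- qcVariants(gMED, preset$qc$mafMin, preset$qc$hetDevMax)
    # true phase of the genotyped animals on the QC-passed medium panel
    lo <- pop@map@loci
    medRows <- match(qMED@loci$id, lo$id)
    cols1 <- hapColOf(pop, genoIds)
    cols <- as.vector(rbind(cols1, cols1 + 1L))
    hapMed <- t(matrix(as.integer(pop@haplo[medRows, cols, drop = FALSE]),
                       length(medRows)))
    ped <- pop@ped
    e <- new.env(parent = emptyenv())
    e$pop <- pop; e$trait <- trait; e$preset <- preset
    e$split <- sp; e$genoIds <- genoIds
    e$qHD <- qHD; e$qMED <- qMED; e$hapMed <- hapMed
    e$Ainv <- aInverse(ped)
    e$A22 <- aSubmatrix(ped, genoIds)
    e$A22inv <- chol2inv(chol(e$A22))
    e$genoIdx <- match(genoIds, ped$id)
    e$blocks <- list()
    e$tbvVal <- pop@tbv[match(sp$validationIds, ped$id)]
    e
  })
}

# blocks + encoded/QCed pseudo-SNPs for a threshold, cached per replicate
.blocksFor <- function(data, threshold) {
  key <- sprintf("%.2f", threshold)
  if (!is.null(data$blocks[[key]])) return(data$blocks[[key]])
  t0 <- proc.time()[3]
  bl <- buildLDBlocks(data$hapMed, data$qMED@loci, threshold,
                      data$preset$windowSnps)
  ps <- psq <- NULL
  if (nrow(bl@blocks)) {
    ps <- encodePseudoSNPs(data$hapMed, bl, data$genoIds)
    psq <- qcPseudoSNPs(ps, data$preset$qc$mafMin,
                        data$preset$qc$hetDevMax)
  }
  blockedCols <- if (nrow(bl@blocks)) sort(unlist(bl@members)) else
    integer(0)
  indepCols <- setdiff(seq_len(ncol(data$qMED@dosages)), blockedCols)
  elapsed <- proc.time()[3] - t0
  res <- list(blocks = bl, ps = ps, psq = psq, indepCols = indepCols,
              summary = blockSummary(if (nrow(bl@blocks)) bl else NULL,
                                     ps, psq, length(indepCols), elapsed))
  data$blocks[[key]] <- res
  res
}

#' Run one prediction scenario
#'
#' Executes the scenario pipeline on prepared replicate data: marker-set
#' assembly (individual SNPs, pseudo-SNPs, or both in one or two genomic
#' relationship matrices), G construction and blending, the A22/G
#' compatibility check, H inverse, REML variance components, the mixed-
#' model solve, and the validation metrics. Failures propagate as status
#' codes, never silently: \code{"skipped_poor_G"} (no usable markers or a
#' poor off-diagonal correlation between G and A22) and
#' \code{"failed_convergence"} (REML or solver did not converge).
#'
#' @param variant one of \code{"snp_hd"}, \code{"snp_medium"},
#'   \code{"ips"}, \code{"ps"}, \code{"ips2h"}.
#' @param data environment from \code{\link{prepareScenarioData}}.
#' @param threshold LD threshold for the block-based variants.
#' @param label scenario label recorded in the result row.
#' @param replicate replicate number recorded in the result row.
#' @return One-row data.frame: scenario, population, h2_level, replicate,
#'   status, accuracy, bias, varG1, varG2, varE, h2_hat, n_markers,
#'   solver_iterations.
#' @export
runScenario <- function(variant, data, threshold = NA, label = variant,
                        replicate = 1L) {
  preset <- data$preset
  pop <- data$pop
  ped <- pop@ped
  row <- data.frame(scenario = label,
                    population = ped$breed[nrow(ped)],
                    h2_level = data$trait@h2, replicate = replicate,
                    status = "ok", accuracy = NA_real_, bias = NA_real_,
                    varG1 = NA_real_, varG2 = NA_real_, varE = NA_real_,
                    h2_hat = NA_real_, n_markers = NA_integer_,
                    solver_iterations = NA_integer_)
  out <- tryCatch({
    mats <- switch(variant,
      snp_hd = list(data$qHD@dosages),
      snp_medium = list(data$qMED@dosages),
      ips = {
        bb <- .blocksFor(data, threshold)
        if (is.null(bb$psq) || ncol(bb$psq@dosages) == 0)
          list(data$qMED@dosages[, bb$indepCols, drop = FALSE])
        else
          list(cbind(data$qMED@dosages[, bb$indepCols, drop = FALSE],
                     bb$psq@dosages))
      },
      ps = {
        bb <- .blocksFor(data, threshold)
        if (is.null(bb$psq) || ncol(bb$psq@dosages) == 0) {
          row$status <- "skipped_poor_G"
          return(row)
        }
        list(bb$psq@dosages)
      },
      ips2h = {
        bb <- .blocksFor(data, threshold)
        if (is.null(bb$psq) || ncol(bb$psq@dosages) == 0) {
          row$status <- "skipped_poor_G"
          return(row)
        }
        list(data$qMED@dosages[, bb$indepCols, drop = FALSE],
             bb$psq@dosages)
      },
      stop("unknown variant '", variant, "'"))
    row$n_markers <- sum(vapply(mats, ncol, 0L))
    HinvList <- vector("list", length(mats))
    for (k in seq_along(mats)) {
      if (ncol(mats[[k]]) == 0) {
        row$status <- "skipped_poor_G"
        return(row)
      }
      G <- gMatrix(mats[[k]])
      bl <- blendGMatrix(G, data$A22, preset$blend$alpha,
                         preset$blend$beta)
      cs <- compatibilityStats(bl$Gb, data$A22, preset$minGACor)
      if (cs$poor) {
        row$status <- "skipped_poor_G"
        return(row)
      }
      HinvList[[k]] <- hInverse(data$Ainv, data$A22inv, bl$GbInv,
                                data$genoIdx, preset$blend$tau,
                                preset$blend$omega)
    }
    rec <- data$split$records
    vc <- estimateVarComps(rec$y, rec$generation, rec$id, ped$id,
                           HinvList, method = preset$solver$remlMethod,
                           tol = preset$solver$remlTol)
    row$varG1 <- vc$varG[1]
    row$varG2 <- if (length(vc$varG) > 1) vc$varG[2] else NA_real_
    row$varE <- vc$varE
    row$h2_hat <- vc$h2
    if (!vc$converged) {
      row$status <- "failed_convergence"
      return(row)
    }
    sol <- solveMME(rec$y, rec$generation, rec$id, ped$id, HinvList,
                    varG = vc$varG, varE = vc$varE, method = "pcg",
                    tol = preset$solver$pcgTol,
                    maxIter = preset$solver$pcgMaxIter)
    row$solver_iterations <- sol@iterations
    if (!sol@converged) {
      row$status <- "failed_convergence"
      return(row)
    }
    gv <- sol@gebv[match(data$split$validationIds, ped$id)]
    row$accuracy <- gebvAccuracy(gv, data$tbvVal)
    row$bias <- gebvBias(gv, data$tbvVal)
    row
  }, error = function(err) {
    row$status <- paste0("error: ", conditionMessage(err))
    row
  })
  out
}

#' Simulate and evaluate one replicate
#'
#' Convenience wrapper: simulates one study population, prepares the
#' shared scenario inputs and runs the requested scenarios.
#'
#' @param population,h2,qtlH2,preset,seed passed to
#'   \code{\link{simulateStudyPopulation}}.
#' @param scenarios subset of \code{\link{markerConfigs}} scenario labels
#'   (default: all eleven).
#' @param replicate replicate number recorded in the rows.
#' @return data.frame with one row per scenario; the block statistics per
#'   threshold are attached as attribute \code{"block_stats"}.
#' @export
runReplicate <- function(population = "Breed_B", h2 = 0.30,
                         qtlH2 = h2 / 2, preset = presetReduced(),
                         seed = 1, scenarios = markerConfigs()$scenario,
                         replicate = 1L) {
  sim <- simulateStudyPopulation(population, h2, qtlH2, preset, seed)
  data <- prepareScenarioData(sim$pop, sim$trait, preset,
                              seed = seed + 1000003L)
  cfg <- markerConfigs()
  cfg <- cfg[cfg$scenario %in% scenarios, ]
  rows <- lapply(seq_len(nrow(cfg)), function(i)
    runScenario(cfg$variant[i], data, cfg$threshold[i], cfg$scenario[i],
                replicate))
  res <- do.call(rbind, rows)
  attr(res, "block_stats") <- lapply(data$blocks, `[[`, "summary")
  res
}

#' Summarise scenario results over replicates
#'
#' @param results data.frame of \code{\link{runScenario}} rows (several
#'   replicates).
#' @return data.frame with mean and SE of accuracy and bias per
#'   (population, h2_level, scenario) over successful replicates, plus
#'   failure/skip counts.
#' @export
summarizeReplicates <- function(results) {
  key <- interaction(results$population, results$h2_level,
                     results$scenario, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    ok <- d$status == "ok"
    se <- function(x) if (sum(ok) > 1) sd(x[ok]) / sqrt(sum(ok)) else
      NA_real_
    data.frame(population = d$population[1], h2_level = d$h2_level[1],
               scenario = d$scenario[1], n_ok = sum(ok),
               n_failed = sum(d$status == "failed_convergence"),
               n_skipped = sum(d$status == "skipped_poor_G"),
               accuracy_mean = if (any(ok)) mean(d$accuracy[ok]) else
                 NA_real_,
               accuracy_se = se(d$accuracy),
               bias_mean = if (any(ok)) mean(d$bias[ok]) else NA_real_,
               bias_se = se(d$bias))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two scenarios across replicates
#'
#' Simple paired t-test on a metric, matching rows by replicate. Shipped
#' as a convenience; the full mixed-model comparison with replicate
#' covariance structures is intentionally out of scope (the per-replicate
#' table feeds any external stats package).
#'
#' @param results replicate rows.
#' @param a,b scenario labels to compare.
#' @param metric \code{"accuracy"} or \code{"bias"}.
#' @return htest object from \code{t.test}.
#' @export
pairedScenarioTest <- function(results, a, b, metric = "accuracy") {
  da <- results[results$scenario == a & results$status == "ok", ]
  db <- results[results$scenario == b & results$status == "ok", ]
  common <- intersect(da$replicate, db$replicate)
  if (length(common) < 2) stop("need >= 2 common successful replicates")
  stats::t.test(da[[metric]][match(common, da$replicate)],
                db[[metric]][match(common, db$replicate)], paired = TRUE)
}
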