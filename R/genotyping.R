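# Genotyping (panel extraction, missingness, genotyping errors) and marker
# quality control.

#' Genotype animals on a marker panel
#'
#' Extracts true dosages (count of the "1" allele) for the HD or medium
#' panel and perturbs them: each call is set missing with probability
#' \code{missingRate}; each remaining call is replaced by a random
#' \emph{different} valid code (0/1/2) with probability \code{errorRate}.
#'
#' @param pop a \linkS4class{Population} with stored haplotypes.
#' @param ids animals to genotype (default: all stored).
#' @param panel \code{"hd"} or \code{"medium"}.
#' @param missingRate,errorRate perturbation rates (defaults 0.05 and
#'   0.01).
#' @param seed optional seed.
#' @return A \linkS4class{GenotypeData}.
#' @export
applyGenotyping <- function(pop, ids = pop@haploIds,
                            panel = c("hd", "medium"), missingRate = 0.05,
                            errorRate = 0.01, seed = NULL) {
  panel <- match.arg(panel)
  .withSeed(seed, {
    lo <- pop@map@loci
    rows <- which(if (panel == "hd") lo$hd else lo$medium)
    if (!length(rows)) stop("panel '", panel, "' is empty; run selectPanels")
    d <- cpp_dosage(pop@haplo, hapColOf(pop, ids), rows)
    if (missingRate > 0) {
      miss <- runif(length(d)) < missingRate
      d[miss] <- NA_integer_
    }
    if (errorRate > 0) {
      err <- which(!is.na(d) & runif(length(d)) < errorRate)
      if (length(err))
        d[err] <- (d[err] + sample.int(2L, length(err),
                                       replace = TRUE)) %% 3L
    }
    storage.mode(d) <- "double"
    new("GenotypeData", dosages = d, ids = as.integer(ids),
        loci = lo[rows, c("chrom", "pos_cM", "pos_bp", "id")],
        panel = panel)
  })
}

#' Marker (and pseudo-SNP) quality control
#'
#' Keeps loci with MAF >= \code{mafMin} and no extreme departure from
#' Hardy-Weinberg equilibrium: the absolute difference between the observed
#' heterozygote frequency and the expected \code{2p(1-p)} must be below
#' \code{hetDevMax}. Pseudo-loci are treated as bi-allelic (the focal
#' haplotype allele versus all others), so the same rules apply unchanged.
#'
#' @param geno a \linkS4class{GenotypeData} (or
#'   \linkS4class{PseudoSNPMatrix}).
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hetDevMax maximum tolerated heterozygosity departure
#'   (default 0.15).
#' @return The filtered object; attribute \code{"qc"} reports the number of
#'   loci removed by each rule and flags an empty result.
#' @export
setGeneric("qcVariants", function(geno, mafMin = 0.01, hetDevMax = 0.15)
  standardGeneric("qcVariants"))

.qcKeep <- function(d, mafMin, hetDevMax) {
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hetObs <- colMeans(abs(d - 1) < 1e-8, na.rm = TRUE)
  hetDev <- abs(hetObs - 2 * p * (1 - p))
  okMaf <- !is.na(maf) & maf >= mafMin
  okHet <- !is.na(hetDev) & hetDev < hetDevMax
  list(keep = okMaf & okHet, nMaf = sum(!okMaf), nHet = sum(!okHet))
}

.qcAttr <- function(x, q) {
  attr(x, "qc") <- list(n_removed_maf = q$nMaf, n_removed_het = q$nHet,
                        n_kept = sum(q$keep), empty = !any(q$keep))
  if (!any(q$keep))
    warning("quality control removed every locus")
  x
}

#' @rdname qcVariants
#' @export
setMethod("qcVariants", "GenotypeData", function(geno, mafMin = 0.01,
                                                 hetDevMax = 0.15) {
  q <- .qcKeep(geno@dosages, mafMin, hetDevMax)
  out <- new("GenotypeData",
             dosages = geno@dosages[, q$keep, drop = FALSE],
             ids = geno@ids, loci = geno@loci[q$keep, , drop = FALSE],
             panel = geno@panel)
  .qcAttr(out, q)
})

#' @rdname qcVariants
#' @export
setMethod("qcVariants", "PseudoSNPMatrix", function(geno, mafMin = 0.01,
                                                    hetDevMax = 0.15) {
  q <- .qcKeep(geno@dosages, mafMin, hetDevMax)
  out <- new("PseudoSNPMatrix",
             dosages = geno@dosages[, q$keep, drop = FALSE],
             ids = geno@ids, loci = geno@loci[q$keep, , drop = FALSE],
             panel = geno@panel, block = geno@block[q$keep],
             alleleLabel = geno@alleleLabel[q$keep])
  .qcAttr(out, q)
})
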