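# S4 classes for the simulated populations, genotype panels, haploblocks and
# mixed-model machinery.

setOldClass("data.frame")

#' Genome and marker-panel configuration
#'
#' Describes the simulated genome: chromosomes, marker/QTL panel sizes, the
#' number of candidate loci simulated so that panels can later be sampled
#' among segregating loci, and per-locus mutation rates. Genetic distance is
#' converted to physical coordinates at \code{cMPerMb} (1 cM = 1 Mb by
#' default, the usual approximation in sheep).
#'
#' @slot chromosomes data.frame with columns \code{chrom} and
#'   \code{length_cM}.
#' @slot cMPerMb cM per Mb ratio used to derive bp positions.
#' @slot nMarkersHD,nMarkersMedium high-density panel size and the size of
#'   the medium panel nested inside it.
#' @slot nQTL number of QTLs placed on the genome.
#' @slot nMarkerCandidates,nQTLCandidates numbers of candidate loci carried
#'   through the historical phase, from which the panels are sampled among
#'   loci still segregating (MAF >= 0.05).
#' @slot markerMutationRate,qtlMutationRate per-locus per-gamete recurrent
#'   mutation rates (applied in the historical phase).
#' @slot qtlAlleleRange inclusive range of QTL allele counts.
#' @exportClass GenomeConfig
setClass("GenomeConfig",
  representation(
    chromosomes = "data.frame",
    cMPerMb = "numeric",
    nMarkersHD = "numeric",
    nMarkersMedium = "numeric",
    nQTL = "numeric",
    nMarkerCandidates = "numeric",
    nQTLCandidates = "numeric",
    markerMutationRate = "numeric",
    qtlMutationRate = "numeric",
    qtlAlleleRange = "numeric"
  )
)

setValidity("GenomeConfig", function(object) {
  ch <- object@chromosomes
  if (!all(c("chrom", "length_cM") %in% names(ch)))
    return("chromosomes needs columns 'chrom' and 'length_cM'")
  if (any(ch$length_cM <= 0)) return("chromosome lengths must be > 0")
  if (object@nMarkersMedium > object@nMarkersHD)
    return("medium panel cannot exceed the HD panel")
  if (object@nMarkerCandidates < object@nMarkersHD)
    return("need at least as many candidate markers as the HD panel")
  if (object@nQTLCandidates < object@nQTL)
    return("need at least as many candidate QTLs as nQTL")
  r <- object@qtlAlleleRange
  if (length(r) != 2 || r[1] < 2 || r[2] < r[1])
    return("qtlAlleleRange must be c(min, max) with min >= 2")
  TRUE
})

#' Genetic map of simulated loci
#'
#' @slot chromosomes data.frame (\code{chrom}, \code{length_cM}).
#' @slot loci data.frame with one row per locus: \code{chrom},
#'   \code{pos_cM}, \code{pos_bp}, \code{type} ("marker"/"qtl"), \code{hd},
#'   \code{medium} (panel membership), \code{n_alleles} and \code{id}. Rows
#'   are ordered by chromosome then position; marker and QTL positions are
#'   disjoint within a chromosome.
#' @slot cMPerMb conversion ratio used for \code{pos_bp}.
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(chromosomes = "data.frame", loci = "data.frame",
                 cMPerMb = "numeric")
)

setValidity("GenomeMap", function(object) {
  lo <- object@loci
  need <- c("chrom", "pos_cM", "pos_bp", "type", "hd", "medium",
            "n_alleles", "id")
  if (!all(need %in% names(lo))) return("loci is missing required columns")
  if (any(lo$medium & !lo$hd)) return("medium panel must nest inside HD")
  for (ch in unique(lo$chrom)) {
    p <- lo$pos_bp[lo$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      return("loci must be strictly ordered by bp position within chromosome")
  }
  if (any(lo$n_alleles < 2)) return("all loci need >= 2 alleles")
  TRUE
})

#' Trait architecture: QTL effects and variance partition
#'
#' The trait has phenotypic variance \code{varPheno} and heritability
#' \code{h2}; a fraction \code{qtlH2} of the phenotypic variance is
#' explained by the simulated QTLs, the remaining genetic variance
#' (\code{varPolygenic} = (h2 - qtlH2) * varPheno) by an infinitesimal
#' polygenic term. Per-allele additive QTL effects are drawn from a gamma
#' distribution (shape 0.4) with random sign and rescaled so the realised
#' QTL variance in the founder generation matches \code{qtlH2 * varPheno}.
#'
#' @slot h2,qtlH2,varPheno,varPolygenic,mu scalars as described above.
#' @slot effects list of numeric vectors (one per QTL, one entry per allele).
#' @slot qtlIndex rows of the map's loci table that are QTLs.
#' @slot scaled TRUE once effects were rescaled on a founder population.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(h2 = "numeric", qtlH2 = "numeric", varPheno = "numeric",
                 varPolygenic = "numeric", mu = "numeric", effects = "list",
                 qtlIndex = "integer", scaled = "logical")
)

setValidity("TraitArchitecture", function(object) {
  if (object@qtlH2 < 0 || object@qtlH2 > object@h2 || object@h2 > 1)
    return("need 0 <= qtlH2 <= h2 <= 1")
  if (object@varPheno <= 0) return("varPheno must be > 0")
  TRUE
})

#' A simulated (or imported) population
#'
#' Holds the pedigree, phased haplotypes, true breeding values and
#' phenotypes. Haplotypes are stored as a raw matrix with loci in rows and
#' two columns per stored individual (\code{haploIds}); haplotypes may be
#' retained for only part of the pedigree (e.g. recent generations).
#'
#' @slot ped data.frame: \code{id}, \code{sire}, \code{dam} (0 = unknown),
#'   \code{sex} (1 male / 2 female), \code{generation} (global counter),
#'   \code{breed}, \code{phase} ("founder", "phenotypic", "random", "ebv",
#'   "historical") and \code{pgen} (generation within phase).
#' @slot map the \linkS4class{GenomeMap}.
#' @slot haplo raw matrix, loci x (2 * length(haploIds)).
#' @slot haploIds ids whose haplotypes are stored, in column order.
#' @slot tbv,polygenic,phenotype numeric vectors aligned with \code{ped}
#'   rows (NA where not assigned).
#' @exportClass Population
setClass("Population",
  representation(ped = "data.frame", map = "GenomeMap", haplo = "matrix",
                 haploIds = "integer", tbv = "numeric",
                 polygenic = "numeric", phenotype = "numeric")
)

setValidity("Population", function(object) {
  ped <- object@ped
  need <- c("id", "sire", "dam", "sex", "generation", "breed", "phase",
            "pgen")
  if (!all(need %in% names(ped))) return("ped is missing required columns")
  n <- nrow(ped)
  if (!identical(ped$id, seq_len(n)))
    return("ped$id must be 1..n in row order (parents before offspring)")
  if (any(ped$sire >= ped$id & ped$sire != 0) ||
      any(ped$dam >= ped$id & ped$dam != 0))
    return("parents must precede offspring")
  if (ncol(object@haplo) != 2L * length(object@haploIds))
    return("haplo must have two columns per stored individual")
  if (nrow(object@haplo) != nrow(object@map@loci))
    return("haplo rows must match the map loci")
  for (s in c("tbv", "polygenic", "phenotype"))
    if (length(slot(object, s)) != n)
      return(sprintf("%s must align with ped rows", s))
  TRUE
})

#' Genotype dosage panel
#'
#' Individuals x loci dosage codes in \{0, 1, 2, NA\} for one marker panel
#' (or pseudo-SNP set).
#'
#' @slot dosages integer matrix, individuals x loci (NA = missing call).
#' @slot ids individual ids (rows).
#' @slot loci data.frame describing the columns (\code{chrom},
#'   \code{pos_bp}, \code{id}, ...).
#' @slot panel "hd", "medium" or "pseudo".
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosages = "matrix", ids = "integer", loci = "data.frame",
                 panel = "character")
)

setValidity("GenotypeData", function(object) {
  if (nrow(object@dosages) != length(object@ids))
    return("one dosage row per individual")
  if (ncol(object@dosages) != nrow(object@loci))
    return("one loci row per dosage column")
  d <- object@dosages
  if (any(!is.na(d) & (d < 0 | d > 2))) return("dosages must be 0/1/2 or NA")
  TRUE
})

#' LD-threshold haplotype blocks
#'
#' Non-overlapping runs of two or more consecutive SNPs selected by the
#' weighted-interval blocking of \code{\link{buildLDBlocks}}.
#'
#' @slot blocks data.frame: \code{chrom}, \code{start_bp}, \code{end_bp},
#'   \code{n_snps}, \code{threshold}.
#' @slot members list of integer vectors: column indices (into the loci the
#'   blocks were built on) of each block's SNPs.
#' @slot loci the loci table the indices refer to.
#' @slot threshold,windowSnps blocking parameters.
#' @exportClass HaploblockSet
setClass("HaploblockSet",
  representation(blocks = "data.frame", members = "list",
                 loci = "data.frame", threshold = "numeric",
                 windowSnps = "numeric")
)

setValidity("HaploblockSet", function(object) {
  if (nrow(object@blocks) != length(object@members))
    return("blocks and members must align")
  ns <- vapply(object@members, length, 1L)
  if (any(ns < 2)) return("a haploblock spans at least two SNPs")
  if (length(object@members) > 1) {
    all_m <- unlist(object@members)
    if (anyDuplicated(all_m)) return("blocks must not overlap")
  }
  TRUE
})

#' Pseudo-SNP dosage matrix
#'
#' One pseudo-locus per distinct haplotype allele per block; an individual's
#' dosage is its count (0/1/2) of that haplotype allele, so dosages within a
#' block sum to 2 per individual.
#'
#' @slot block originating block index per pseudo-locus.
#' @slot alleleLabel haplotype allele string per pseudo-locus.
#' @exportClass PseudoSNPMatrix
setClass("PseudoSNPMatrix",
  contains = "GenotypeData",
  representation(block = "integer", alleleLabel = "character")
)

#' Relationship matrices for ssGBLUP
#'
#' @slot Ainv sparse inverse pedigree relationship matrix (all animals).
#' @slot A22 pedigree relationships among genotyped animals.
#' @slot G raw VanRaden genomic relationship matrix.
#' @slot Gb,GbInv blended matrix alpha*G + beta*A22 and its inverse.
#' @slot Hinv single-step combined inverse.
#' @slot genoIds ids of the genotyped animals (order of G/A22 rows).
#' @slot alpha,beta,tau,omega blending and weighting parameters.
#' @exportClass RelationshipSet
setClass("RelationshipSet",
  representation(Ainv = "Matrix", A22 = "matrix", G = "matrix",
                 Gb = "matrix", GbInv = "matrix", Hinv = "Matrix",
                 genoIds = "integer", alpha = "numeric", beta = "numeric",
                 tau = "numeric", omega = "numeric")
)

#' Mixed-model solution report
#'
#' @slot fixed fixed-effect solutions (named).
#' @slot u random-effect solutions, one column per genetic component.
#' @slot gebv total genomic breeding value per animal (row sums of u).
#' @slot ids animal ids for the rows of \code{u}.
#' @slot iterations,converged,finalResidualNorm solver diagnostics.
#' @exportClass SolveReport
setClass("SolveReport",
  representation(fixed = "numeric", u = "matrix", gebv = "numeric",
                 ids = "integer", iterations = "integer",
                 converged = "logical", finalResidualNorm = "numeric")
)

setValidity("SolveReport", function(object) {
  if (object@converged && !is.finite(object@finalResidualNorm))
    return("a converged report needs a finite residual norm")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "GenomeConfig", function(object) {
  cat(sprintf("GenomeConfig: %d chromosomes, %.0f cM total\n",
              nrow(object@chromosomes), sum(object@chromosomes$length_cM)))
  cat(sprintf("  panels: HD %d / medium %d markers, %d QTLs (%d/%d candidates)\n",
              as.integer(object@nMarkersHD), as.integer(object@nMarkersMedium),
              as.integer(object@nQTL), as.integer(object@nMarkerCandidates),
              as.integer(object@nQTLCandidates)))
})

setMethod("show", "GenomeMap", function(object) {
  lo <- object@loci
  cat(sprintf("GenomeMap: %d loci (%d markers [HD %d, medium %d], %d QTLs) on %d chromosomes\n",
              nrow(lo), sum(lo$type == "marker"), sum(lo$hd),
              sum(lo$medium), sum(lo$type == "qtl"),
              nrow(object@chromosomes)))
})

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(
    "TraitArchitecture: h2 %.2f (QTL %.2f), varP %.0f, polygenic var %.1f, %d QTLs%s\n",
    object@h2, object@qtlH2, object@varPheno, object@varPolygenic,
    length(object@effects), if (object@scaled) " (scaled)" else ""))
})

setMethod("show", "Population", function(object) {
  ped <- object@ped
  cat(sprintf("Population: %d animals (%s), %d with stored haplotypes\n",
              nrow(ped), paste(unique(ped$breed), collapse = "/"),
              length(object@haploIds)))
  tab <- table(ped$phase)
  cat("  phases:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  phenotyped: %d, mean TBV %.3f\n",
              sum(!is.na(object@phenotype)),
              mean(object@tbv, na.rm = TRUE)))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData (%s): %d individuals x %d loci, %.2f%% missing\n",
              object@panel, nrow(object@dosages), ncol(object@dosages),
              100 * mean(is.na(object@dosages))))
})

setMethod("show", "PseudoSNPMatrix", function(object) {
  cat(sprintf("PseudoSNPMatrix: %d individuals x %d pseudo-loci from %d blocks\n",
              nrow(object@dosages), ncol(object@dosages),
              length(unique(object@block))))
})

setMethod("show", "HaploblockSet", function(object) {
  cat(sprintf("HaploblockSet: %d blocks (r2 >= %.2f), %d SNPs blocked\n",
              nrow(object@blocks), object@threshold,
              sum(object@blocks$n_snps)))
})

setMethod("show", "RelationshipSet", function(object) {
  cat(sprintf(
    "RelationshipSet: %d animals (%d genotyped); alpha=%.2f beta=%.2f tau=%.1f omega=%.1f\n",
    nrow(object@Ainv), length(object@genoIds), object@alpha, object@beta,
    object@tau, object@omega))
})

setMethod("show", "SolveReport", function(object) {
  cat(sprintf("SolveReport: %d animals, %d component(s); %s in %d iterations (residual %.2e)\n",
              length(object@gebv), ncol(object@u),
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@finalResidualNorm))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for hapstep objects
#'
#' @param x an object from this package.
#' @return \code{pedigree} the pedigree data.frame; \code{haplotypes} the raw
#'   phased haplotype matrix (loci x 2 per stored individual);
#'   \code{dosages} the dosage matrix; \code{tbv}/\code{phenotypes} numeric
#'   vectors aligned with the pedigree; \code{lociInfo} the loci table;
#'   \code{blockTable} the block summary data.frame; \code{gebv} the total
#'   genomic breeding values of a \linkS4class{SolveReport}.
#' @name accessors
#' @aliases pedigree haplotypes dosages tbv phenotypes lociInfo blockTable
#'   gebv
NULL

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname accessors
#' @export
setMethod("pedigree", "Population", function(x) x@ped)

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setMethod("haplotypes", "Population", function(x) x@haplo)

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("tbv", function(x) standardGeneric("tbv"))
#' @rdname accessors
#' @export
setMethod("tbv", "Population", function(x) x@tbv)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setMethod("phenotypes", "Population", function(x) x@phenotype)

#' @rdname accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))
#' @rdname accessors
#' @export
setMethod("lociInfo", "GenomeMap", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("lociInfo", "Population", function(x) x@map@loci)
#' @rdname accessors
#' @export
setMethod("lociInfo", "GenotypeData", function(x) x@loci)

#' @rdname accessors
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))
#' @rdname accessors
#' @export
setMethod("blockTable", "HaploblockSet", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setMethod("gebv", "SolveReport", function(x) setNames(x@gebv, x@ids))

#' @rdname accessors
#' @export
setGeneric("genomeMap", function(x) standardGeneric("genomeMap"))
#' @rdname accessors
#' @export
setMethod("genomeMap", "Population", function(x) x@map)

# Internal: haplotype columns of given ids (first column per individual).
hapColOf <- function(pop, ids) {
  idx <- match(ids, pop@haploIds)
  if (anyNA(idx))
    stop("haplotypes not stored for ids: ",
         paste(head(ids[is.na(idx)]), collapse = ", "))
  2L * idx - 1L
}
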