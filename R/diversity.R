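# Linkage disequilibrium and effective population size estimators.

#' Expected LD for a population of effective size Ne
#'
#' Sved's expectation \code{E(r2) = 1 / (4 Ne c + 2)} for loci separated by
#' a genetic distance \code{c} (Morgans).
#'
#' @param Ne effective population size (> 0).
#' @param c genetic distance in Morgans (>= 0).
#' @return Expected r2 (vectorised).
#' @export
expectedR2 <- function(Ne, c) {
  stopifnot(all(Ne > 0), all(c >= 0))
  1 / (4 * Ne * c + 2)
}

#' Effective population size from observed LD
#'
#' Inverts the Sved expectation:
#' \code{Ne = (4c)^-1 (1 / mean_r2 - 2)}. The estimate refers to the
#' population \code{t = 1/(2c)} generations ago.
#'
#' @param meanR2 mean observed r2 at distance \code{c} (0 < meanR2 <= 1).
#' @param c genetic distance in Morgans (> 0).
#' @return data.frame(method, c, mean_r2, Ne, t).
#' @export
neFromLD <- function(meanR2, c) {
  if (any(c <= 0)) stop("c must be > 0")
  if (any(meanR2 <= 0 | meanR2 > 1)) stop("meanR2 must be in (0, 1]")
  if (any(meanR2 >= 0.5))
    stop("mean r2 >= 0.5 implies a non-positive Ne under the Sved ",
         "expectation; the LD estimator is undefined here")
  data.frame(method = "LD", c = c, mean_r2 = meanR2,
             Ne = (1 / (4 * c)) * (1 / meanR2 - 2),
             t = generationsFromDistance(c))
}

#' Generation horizon of an LD-based Ne estimate
#'
#' \code{t = 1 / (2c)}: the Ne estimated from LD at distance \code{c}
#' existed about \code{t} generations ago (10 Mb, i.e. c = 0.1 M, is about
#' five generations ago and is taken as the current Ne).
#'
#' @param c genetic distance in Morgans (> 0).
#' @return Number of generations ago.
#' @export
generationsFromDistance <- function(c) {
  if (any(c <= 0)) stop("c must be > 0")
  1 / (2 * c)
}

#' Pairwise r2 between loci
#'
#' With phased input the squared correlation of allele indicators across
#' gametes is computed, which equals \code{D^2 / (pA qA pB qB)} from the
#' 2x2 haplotype table; with dosage input the squared correlation of
#' dosages is used instead. Pairs involving loci that fail the MAF filter
#' (or are monomorphic) are skipped and reported.
#'
#' @param x matrix: gametes x loci of 0/1 alleles (\code{type = "phased"})
#'   or individuals x loci of 0/1/2 dosages (\code{type = "dosage"}).
#' @param pairs two-column matrix of column indices; pairs should lie
#'   within a chromosome.
#' @param mafMin minimum allele frequency (default 0.05, the usual LD
#'   filter).
#' @param type input type.
#' @return data.frame(i, j, r2); attribute \code{"skipped"} counts the
#'   pairs excluded by the MAF filter.
#' @export
pairwiseR2 <- function(x, pairs, mafMin = 0.05,
                       type = c("phased", "dosage")) {
  type <- match.arg(type)
  if (type == "phased" && !all(x %in% c(0, 1)))
    stop("phased input must be a 0/1 allele matrix")
  pairs <- matrix(as.integer(pairs), ncol = 2)
  p <- colMeans(x) / (if (type == "phased") 1 else 2)
  ok <- pmin(p, 1 - p) >= mafMin
  keep <- ok[pairs[, 1]] & ok[pairs[, 2]]
  skipped <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    cor(x[, pairs[k, 1]], x[, pairs[k, 2]])^2
  }, 0)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], r2 = r2)
  attr(out, "skipped") <- skipped
  out
}

#' Mean r2 at a target genetic distance
#'
#' Averages \code{\link{pairwiseR2}} over all within-chromosome marker
#' pairs whose distance falls within \code{window} (a fraction) of the
#' target \code{c}; optionally averaged per chromosome first.
#'
#' @param hap gametes x loci phased 0/1 matrix.
#' @param loci data.frame with \code{chrom} and \code{pos_cM} for the
#'   columns of \code{hap}.
#' @param targetC target distance in Morgans (default 0.1, i.e. 10 Mb).
#' @param window half-width of the distance window as a fraction of
#'   \code{targetC} (default 0.05).
#' @param mafMin MAF filter (default 0.05).
#' @param average \code{"pairs"} pools all pairs; \code{"chromosome"}
#'   averages within chromosome and then across chromosomes.
#' @return list(mean_r2, n_pairs, c).
#' @export
meanR2AtDistance <- function(hap, loci, targetC = 0.1, window = 0.05,
                             mafMin = 0.05,
                             average = c("pairs", "chromosome")) {
  average <- match.arg(average)
  lo <- targetC * (1 - window) * 100
  hi <- targetC * (1 + window) * 100
  perChrom <- lapply(unique(loci$chrom), function(ch) {
    cols <- which(loci$chrom == ch)
    if (length(cols) < 2) return(NULL)
    pos <- loci$pos_cM[cols]
    dd <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(dd) & dd >= lo & dd <= hi, arr.ind = TRUE)
    if (!nrow(sel)) return(NULL)
    pairwiseR2(hap[, cols, drop = FALSE],
               cbind(sel[, 1], sel[, 2]), mafMin = mafMin)
  })
  perChrom <- Filter(function(d) !is.null(d) && nrow(d) > 0, perChrom)
  if (!length(perChrom))
    stop("no marker pairs found in the distance window around c = ",
         targetC)
  if (average == "pairs") {
    all <- do.call(rbind, perChrom)
    list(mean_r2 = mean(all$r2), n_pairs = nrow(all), c = targetC)
  } else {
    ms <- vapply(perChrom, function(d) mean(d$r2), 0)
    list(mean_r2 = mean(ms),
         n_pairs = sum(vapply(perChrom, nrow, 0L)), c = targetC)
  }
}

#' Effective population size from the realised rate of inbreeding
#'
#' \code{Ne = 1 / (2 dF)} with
#' \code{dF = (F_n - F_{n-1}) / (1 - F_{n-1})} computed from the last two
#' consecutive generation means of pedigree inbreeding.
#'
#' @param Fbar numeric vector of mean inbreeding per generation (ordered,
#'   length >= 2).
#' @return data.frame(method, dF, Ne).
#' @export
neFromInbreeding <- function(Fbar) {
  if (length(Fbar) < 2) stop("need mean inbreeding for >= 2 generations")
  n <- length(Fbar)
  dF <- (Fbar[n] - Fbar[n - 1]) / (1 - Fbar[n - 1])
  if (!is.finite(dF) || dF <= 0)
    stop("non-positive rate of inbreeding (dF = ", signif(dF, 3),
         "); Ne from inbreeding is undefined")
  data.frame(method = "inbreeding", dF = dF, Ne = 1 / (2 * dF))
}

#' Ne report for a population
#'
#' Combines the LD-based estimate (mean r2 at \code{targetC} among stored
#' haplotypes of the latest generations) and, when a pedigree with several
#' generations is available, the inbreeding-based estimate, in the TSV
#' layout \code{method, c, mean_r2, Ne, t}.
#'
#' @param pop a \linkS4class{Population}.
#' @param ids animals whose haplotypes enter the LD estimate (default: the
#'   latest generation).
#' @param targetC,window,mafMin see \code{\link{meanR2AtDistance}}.
#' @return data.frame with one row per method.
#' @export
neReport <- function(pop, ids = NULL, targetC = 0.1, window = 0.05,
                     mafMin = 0.05) {
  ped <- pop@ped
  if (is.null(ids))
    ids <- intersect(ped$id[ped$generation == max(ped$generation)],
                     pop@haploIds)
  lo <- pop@map@loci
  mrows <- which(lo$type == "marker")
  cols1 <- hapColOf(pop, ids)
  cols <- as.vector(rbind(cols1, cols1 + 1L))
  hap <- t(matrix(as.integer(pop@haplo[mrows, cols, drop = FALSE]),
                  length(mrows)))
  m <- meanR2AtDistance(hap, lo[mrows, ], targetC, window, mafMin)
  out <- neFromLD(m$mean_r2, targetC)
  gens <- sort(unique(ped$generation))
  if (length(gens) >= 2) {
    Fv <- pedigreeInbreeding(ped)
    Fbar <- vapply(gens, function(g) mean(Fv[ped$generation == g]), 0)
    inb <- tryCatch(neFromInbreeding(Fbar), error = function(e) NULL)
    if (!is.null(inb))
      out <- rbind(out, data.frame(method = "inbreeding", c = NA,
                                   mean_r2 = NA, Ne = inb$Ne,
                                   t = generationsFromDistance(targetC)))
  }
  out
}
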