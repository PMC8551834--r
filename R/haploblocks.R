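# LD-threshold haplotype blocks, pseudo-SNP encoding and block statistics.

# banded r2: band[[d]][k] = r2 between SNP k and SNP k+d (within one
# chromosome), computed from the phased allele matrix
.r2Band <- function(hap, window) {
  m <- ncol(hap)
  n <- nrow(hap)
  Xc <- scale(hap)  # columns with zero variance give NaN, handled below
  band <- vector("list", min(window - 1L, m - 1L))
  for (d in seq_along(band)) {
    k <- seq_len(m - d)
    r <- colSums(Xc[, k, drop = FALSE] * Xc[, k + d, drop = FALSE]) /
      (n - 1)
    band[[d]] <- r^2
  }
  band
}

#' Build LD-threshold haplotype blocks
#'
#' Within a sliding window of \code{windowSnps} consecutive SNPs, every
#' candidate interval of two or more SNPs is tested: it is valid if each
#' member SNP has r2 >= \code{r2Threshold} with at least one other member
#' and the interval's mean pairwise r2 is >= \code{r2Threshold}. A
#' non-overlapping set of valid intervals maximising the total number of
#' SNPs covered is then selected by weighted-interval-scheduling dynamic
#' programming (ties broken by earlier start, then longer interval).
#' Singletons are never blocks.
#'
#' @param hap phased allele matrix (gametes x SNPs, 0/1); two consecutive
#'   rows per individual.
#' @param loci data.frame describing the SNP columns (\code{chrom},
#'   \code{pos_bp}).
#' @param r2Threshold LD threshold (study levels 0.1, 0.3, 0.6).
#' @param windowSnps sliding-window width in SNPs (default 100).
#' @return A \linkS4class{HaploblockSet}.
#' @export
buildLDBlocks <- function(hap, loci, r2Threshold, windowSnps = 100) {
  if (!all(hap %in% c(0, 1)))
    stop("blocking needs phased 0/1 haplotypes (unphased input rejected)")
  if (r2Threshold <= 0 || r2Threshold >= 1)
    stop("r2Threshold must be in (0, 1)")
  stopifnot(ncol(hap) == nrow(loci))
  blocksL <- list(); membersL <- list()
  for (ch in unique(loci$chrom)) {
    cols <- which(loci$chrom == ch)
    m <- length(cols)
    if (m < 2) next
    band <- .r2Band(hap[, cols, drop = FALSE], windowSnps)
    iv <- .candidateIntervals(band, m, r2Threshold, windowSnps)
    sel <- .selectIntervals(iv, m)
    for (r in seq_len(nrow(sel))) {
      mem <- cols[sel$i[r]:sel$j[r]]
      membersL[[length(membersL) + 1L]] <- mem
      blocksL[[length(blocksL) + 1L]] <- data.frame(
        chrom = ch, start_bp = loci$pos_bp[mem[1]],
        end_bp = loci$pos_bp[mem[length(mem)]], n_snps = length(mem),
        threshold = r2Threshold)
    }
  }
  blocks <- if (length(blocksL)) do.call(rbind, blocksL) else
    data.frame(chrom = integer(0), start_bp = integer(0),
               end_bp = integer(0), n_snps = integer(0),
               threshold = numeric(0))
  new("HaploblockSet", blocks = blocks, members = membersL, loci = loci,
      threshold = r2Threshold, windowSnps = windowSnps)
}

# enumerate valid intervals [i..j] (see buildLDBlocks) from the banded r2
.candidateIntervals <- function(band, m, thr, window) {
  wlen <- length(band)
  R2w <- matrix(0, m, wlen)  # R2w[k, d] = r2(k, k+d); 0 where undefined
  for (d in seq_len(wlen)) {
    vals <- band[[d]]
    vals[is.na(vals)] <- 0
    R2w[seq_len(m - d), d] <- vals
  }
  valid <- matrix(FALSE, m, wlen)  # valid[i, j - i]
  for (i in seq_len(m - 1L)) {
    jmax <- min(m, i + window - 1L)
    if (jmax <= i) next
    sumr2 <- 0
    maxlink <- rep(-Inf, jmax - i + 1L)  # local index 1..(j-i+1)
    for (j in (i + 1L):jmax) {
      ks <- i:(j - 1L)
      v <- R2w[cbind(ks, j - ks)]
      sumr2 <- sumr2 + sum(v)
      li <- seq_len(j - i)
      maxlink[li] <- pmax(maxlink[li], v)
      maxlink[j - i + 1L] <- max(v)
      npairs <- (j - i + 1L) * (j - i) / 2
      valid[i, j - i] <- sumr2 / npairs >= thr &&
        min(maxlink[seq_len(j - i + 1L)]) >= thr
    }
  }
  sel <- which(valid, arr.ind = TRUE)
  data.frame(i = as.integer(sel[, 1]),
             j = as.integer(sel[, 1] + sel[, 2]))
}

# weighted-interval scheduling maximising covered SNPs; reconstruction
# prefers earlier starts, then longer intervals
.selectIntervals <- function(iv, m) {
  if (!nrow(iv)) return(data.frame(i = integer(0), j = integer(0)))
  w <- iv$j - iv$i + 1L
  opt <- integer(m + 2L)  # opt[i] = best coverage using SNPs i..m
  byStart <- split(seq_len(nrow(iv)), factor(iv$i, levels = seq_len(m)))
  for (i in m:1) {
    best <- opt[i + 1L]
    for (k in byStart[[i]])
      best <- max(best, w[k] + opt[iv$j[k] + 1L])
    opt[i] <- best
  }
  res_i <- integer(0); res_j <- integer(0)
  i <- 1L
  while (i <= m) {
    cand <- byStart[[i]]
    if (length(cand)) {
      attain <- cand[w[cand] + opt[iv$j[cand] + 1L] == opt[i]]
      if (length(attain)) {
        k <- attain[which.max(iv$j[attain])]
        res_i <- c(res_i, iv$i[k]); res_j <- c(res_j, iv$j[k])
        i <- iv$j[k] + 1L
        next
      }
    }
    i <- i + 1L
  }
  data.frame(i = res_i, j = res_j)
}

#' Encode haplotype alleles as pseudo-SNPs
#'
#' For each block, the distinct haplotype strings observed among the
#' supplied gametes become pseudo-loci; an individual's dosage at a
#' pseudo-locus is the number of copies (0/1/2) of that haplotype allele it
#' carries, so dosages within a block sum to 2. Gametes with missing
#' alleles inside a block contribute the allele-frequency expectation
#' instead (mean imputation, flagged via attribute \code{"imputed"}).
#'
#' @param hap phased allele matrix (gametes x SNPs) aligned with
#'   \code{blocks@loci}; rows 2i-1 and 2i belong to individual i.
#' @param blocks a \linkS4class{HaploblockSet}.
#' @param ids individual ids (length \code{nrow(hap)/2}).
#' @return A \linkS4class{PseudoSNPMatrix}.
#' @export
encodePseudoSNPs <- function(hap, blocks, ids) {
  stopifnot(nrow(hap) == 2 * length(ids))
  n <- length(ids)
  nb <- length(blocks@members)
  dosL <- list(); lociL <- list(); blkL <- list(); labL <- list()
  nImputed <- 0L
  for (b in seq_len(nb)) {
    mem <- blocks@members[[b]]
    sub <- hap[, mem, drop = FALSE]
    strs <- do.call(paste0, as.data.frame(sub))
    missing <- rowSums(is.na(sub)) > 0
    lev <- sort(unique(strs[!missing]))
    if (!length(lev)) next
    f <- match(strs, lev)
    dos <- matrix(0, n, length(lev))
    odd <- 2L * seq_len(n) - 1L
    for (hcol in 0:1) {
      fi <- f[odd + hcol]
      okr <- !is.na(fi) & !missing[odd + hcol]
      dos[cbind(which(okr), fi[okr])] <- dos[cbind(which(okr),
                                                   fi[okr])] + 1
    }
    bad <- missing[odd] | missing[odd + 1L]
    if (any(bad)) {
      freq <- colSums(dos[!bad, , drop = FALSE])
      freq <- freq / sum(freq)
      dos[bad, ] <- matrix(2 * freq, sum(bad), length(lev), byrow = TRUE)
      nImputed <- nImputed + sum(bad)
    }
    dosL[[length(dosL) + 1L]] <- dos
    lociL[[length(lociL) + 1L]] <- data.frame(
      chrom = blocks@blocks$chrom[b],
      pos_cM = NA_real_, pos_bp = blocks@blocks$start_bp[b],
      id = paste0("PS_", b, "_", seq_along(lev)))
    blkL[[length(blkL) + 1L]] <- rep(b, length(lev))
    labL[[length(labL) + 1L]] <- lev
  }
  if (!length(dosL)) {
    out <- new("PseudoSNPMatrix",
               dosages = matrix(numeric(0), n, 0), ids = as.integer(ids),
               loci = data.frame(chrom = integer(0), pos_cM = numeric(0),
                                 pos_bp = integer(0), id = character(0)),
               panel = "pseudo", block = integer(0),
               alleleLabel = character(0))
    attr(out, "imputed") <- 0L
    return(out)
  }
  out <- new("PseudoSNPMatrix", dosages = do.call(cbind, dosL),
             ids = as.integer(ids), loci = do.call(rbind, lociL),
             panel = "pseudo", block = as.integer(unlist(blkL)),
             alleleLabel = unlist(labL))
  attr(out, "imputed") <- nImputed
  out
}

#' Quality control of pseudo-SNPs
#'
#' Applies the same rules as \code{\link{qcVariants}} (MAF and
#' heterozygosity departure, each pseudo-locus treated as bi-allelic).
#'
#' @param ps a \linkS4class{PseudoSNPMatrix}.
#' @param mafMin,hetDevMax thresholds as in \code{\link{qcVariants}}.
#' @return The filtered \linkS4class{PseudoSNPMatrix}.
#' @export
qcPseudoSNPs <- function(ps, mafMin = 0.01, hetDevMax = 0.15) {
  qcVariants(ps, mafMin = mafMin, hetDevMax = hetDevMax)
}

#' Block and pseudo-SNP summary statistics
#'
#' The per-scenario statistics reported for blocking strategies: number of
#' multi-SNP blocks, SNPs inside blocks, pseudo-SNPs before and after QC,
#' and non-blocked SNPs plus pseudo-SNPs after QC.
#'
#' @param blocks a \linkS4class{HaploblockSet} (or NULL for none).
#' @param psBefore,psAfter pseudo-SNP matrices before and after QC (NULL
#'   when no blocks were formed).
#' @param nIndependentSnps number of QC-passed SNPs outside any block.
#' @param elapsed optional wall time (seconds) of blocking + encoding.
#' @return One-row data.frame: \code{n_blocks}, \code{n_blocked_snps},
#'   \code{n_pseudo}, \code{n_pseudo_after_qc},
#'   \code{n_nonblocked_plus_pseudo_after_qc}, \code{elapsed_s}.
#' @export
blockSummary <- function(blocks, psBefore = NULL, psAfter = NULL,
                         nIndependentSnps, elapsed = NA_real_) {
  nb <- if (is.null(blocks)) 0L else nrow(blocks@blocks)
  nbs <- if (is.null(blocks)) 0L else sum(blocks@blocks$n_snps)
  np <- if (is.null(psBefore)) 0L else ncol(psBefore@dosages)
  npa <- if (is.null(psAfter)) 0L else ncol(psAfter@dosages)
  data.frame(n_blocks = nb, n_blocked_snps = nbs, n_pseudo = np,
             n_pseudo_after_qc = npa,
             n_nonblocked_plus_pseudo_after_qc = nIndependentSnps + npa,
             elapsed_s = elapsed)
}
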