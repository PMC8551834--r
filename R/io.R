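# Plain-text interchange: phased VCF, pedigree CSV, phenotype TSV, block
# tables and the simulation manifest.

#' Write phased marker genotypes as VCF 4.2
#'
#' Bi-allelic markers only (alleles written as A/B), GT phased
#' (\code{"0|1"}).
#'
#' @param pop a \linkS4class{Population}.
#' @param file output path.
#' @param ids animals to write (default: all with stored haplotypes).
#' @export
writePhasedVCF <- function(pop, file, ids = pop@haploIds) {
  lo <- pop@map@loci
  rows <- which(lo$type == "marker" & (lo$hd | lo$medium))
  if (!length(rows)) rows <- which(lo$type == "marker")
  cols1 <- hapColOf(pop, ids)
  h1 <- matrix(as.integer(pop@haplo[rows, cols1, drop = FALSE]),
               length(rows))
  h2 <- matrix(as.integer(pop@haplo[rows, cols1 + 1L, drop = FALSE]),
               length(rows))
  gt <- matrix(paste0(h1, "|", h2), length(rows))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapstep",
           sprintf("##contig=<ID=%s,length=%d>",
                   pop@map@chromosomes$chrom,
                   round(pop@map@chromosomes$length_cM /
                           pop@map@cMPerMb * 1e6)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ID", ids)), collapse = "\t"))
  body <- paste(lo$chrom[rows], lo$pos_bp[rows], lo$id[rows], "A", "B",
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read a phased VCF into a haplotype matrix
#'
#' @param file VCF path (plain or bgzipped; parsed with vcfR).
#' @return list with \code{hap} (gametes x loci 0/1 matrix, two
#'   consecutive rows per sample; NA for missing alleles), \code{loci}
#'   (chrom, pos_bp, id) and \code{samples}.
#' @export
readPhasedVCF <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  nS <- ncol(gt); nL <- nrow(gt)
  a1 <- matrix(substr(gt, 1, 1), nL, nS)
  sep <- substr(gt, 2, 2)
  a2 <- matrix(substr(gt, 3, 3), nL, nS)
  if (any(sep == "/", na.rm = TRUE))
    warning("unphased genotypes present; treating '/' alleles as phased")
  toNum <- function(a) matrix(suppressWarnings(as.integer(a)), nL, nS)
  hap <- matrix(NA_integer_, 2L * nS, nL)
  hap[seq(1, 2 * nS, 2), ] <- t(toNum(a1))
  hap[seq(2, 2 * nS, 2), ] <- t(toNum(a2))
  list(hap = hap,
       loci = data.frame(chrom = fix[, "CHROM"],
                         pos_bp = as.integer(fix[, "POS"]),
                         id = fix[, "ID"]),
       samples = colnames(gt))
}

#' Pedigree CSV (id, sire, dam, sex, generation, breed; 0 = unknown)
#'
#' @param ped a \linkS4class{Population} or pedigree data.frame.
#' @param file path.
#' @export
writePedigree <- function(ped, file) {
  pd <- if (is(ped, "Population")) ped@ped else ped
  write.table(pd[, c("id", "sire", "dam", "sex", "generation", "breed")],
              file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(file) {
  read.table(file, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Phenotype TSV (id, generation, phenotype, tbv)
#'
#' @param pop a \linkS4class{Population}.
#' @param file path.
#' @param ids animals to write (default: phenotyped animals).
#' @export
writePhenotypes <- function(pop, file,
                            ids = pop@ped$id[!is.na(pop@phenotype)]) {
  k <- match(ids, pop@ped$id)
  write.table(data.frame(id = ids,
                         generation = pop@ped$generation[k],
                         phenotype = pop@phenotype[k],
                         tbv = pop@tbv[k]),
              file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write haploblocks as a BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, n_snps, n_alleles (when encoded),
#' threshold.
#'
#' @param blocks a \linkS4class{HaploblockSet}.
#' @param file path.
#' @param ps optional \linkS4class{PseudoSNPMatrix} supplying per-block
#'   allele counts.
#' @export
writeBlocks <- function(blocks, file, ps = NULL) {
  b <- blocks@blocks
  b$n_alleles <- if (!is.null(ps))
    as.integer(table(factor(ps@block, levels = seq_len(nrow(b)))))
  else NA_integer_
  write.table(b[, c("chrom", "start_bp", "end_bp", "n_snps", "n_alleles",
                    "threshold")],
              file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a simulated population to an output directory
#'
#' Emits the phased VCF, pedigree CSV, phenotype TSV and a manifest
#' recording the seed and key configuration values.
#'
#' @param pop a \linkS4class{Population}.
#' @param dir output directory (created if needed).
#' @param seedInfo named list recorded in the manifest.
#' @export
writeSimulation <- function(pop, dir, seedInfo = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePhasedVCF(pop, file.path(dir, "genotypes.vcf"))
  writePedigree(pop, file.path(dir, "pedigree.csv"))
  writePhenotypes(pop, file.path(dir, "phenotypes.tsv"))
  mf <- c(sprintf("package=hapstep %s",
                  as.character(utils::packageVersion("hapstep"))),
          sprintf("date=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
          sprintf("n_animals=%d", nrow(pop@ped)),
          sprintf("n_loci=%d", nrow(pop@map@loci)),
          vapply(names(seedInfo), function(k)
            sprintf("%s=%s", k, as.character(seedInfo[[k]])), ""))
  writeLines(mf, file.path(dir, "manifest.txt"))
  invisible(dir)
}
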