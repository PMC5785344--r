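#' Genome model for a biparental cross
#'
#' A `genome_model` bundles the chromosome table (physical and genetic
#' lengths) with the founder marker map: the set of sites that distinguish
#' the donor parent from the recurrent parent, each carrying exactly two
#' distinct single-nucleotide alleles.
#'
#' Coordinates are 1-based inclusive base pairs throughout the package.
#' The recurrent parent is used as the reference genome, so the recurrent
#' allele at every founder site is the reference allele.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp`
#'   (physical length, bp) and `length_cM` (genetic length, centimorgans).
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `donor` and `recurrent` (single-nucleotide alleles, distinct).
#'   Positions must be strictly increasing within a chromosome and lie in
#'   `[1, length_bp]`.
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes` and `sites`.
#' @examples
#' g <- genome_model(
#'   data.frame(name = "chr1", length_bp = 1e6, length_cM = 5),
#'   data.frame(chrom = "chr1", pos = c(1e5, 5e5), donor = "A", recurrent = "G")
#' )
#' @export
genome_model <- function(chromosomes, sites) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(sites))
  need_c <- c("name", "length_bp", "length_cM")
  if (!all(need_c %in% names(chromosomes))) {
    stop("`chromosomes` needs columns: ", paste(need_c, collapse = ", "))
  }
  need_s <- c("chrom", "pos", "donor", "recurrent")
  if (!all(need_s %in% names(sites))) {
    stop("`sites` needs columns: ", paste(need_s, collapse = ", "))
  }
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (any(chromosomes$length_bp <= 0)) stop("chromosome physical length must be > 0")
  if (any(chromosomes$length_cM < 0)) stop("chromosome genetic length must be >= 0")
  if (!all(sites$chrom %in% chromosomes$name)) {
    stop("site chromosome not in chromosome table")
  }
  nuc <- c("A", "C", "G", "T")
  if (!all(sites$donor %in% nuc) || !all(sites$recurrent %in% nuc)) {
    stop("alleles must be single nucleotides A/C/G/T")
  }
  if (any(sites$donor == sites$recurrent)) {
    stop("donor and recurrent alleles must differ at every site")
  }
  sites <- sites[order(match(sites$chrom, chromosomes$name), sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  for (cn in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cn]
    len <- chromosomes$length_bp[chromosomes$name == cn]
    if (any(p < 1) || any(p > len)) stop("site position outside chromosome: ", cn)
    if (any(diff(p) <= 0)) stop("site positions must be strictly increasing on ", cn)
  }
  structure(list(chromosomes = chromosomes, sites = sites),
            class = "genome_model")
}

#' @exportS3Method base::print
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$sites), "founder sites\n")
  cat(sprintf("  total %.1f Mbp / %.0f cM\n",
              sum(x$chromosomes$length_bp) / 1e6, sum(x$chromosomes$length_cM)))
  invisible(x)
}

# IRGSP-1.0-like chromosome physical lengths (Mbp), rounded
.rice_chrom_mbp <- c(43.27, 35.94, 36.41, 35.50, 29.96, 31.25,
                     29.70, 28.44, 23.01, 23.21, 29.02, 27.53)

#' Default rice-like genome for the interspecific cross simulator
#'
#' Builds a 12-chromosome genome with IRGSP-like physical lengths, a uniform
#' physical-to-genetic scale (default 4.76 cM/Mbp, so that a 2.1 Mbp block
#' corresponds to about 10 cM), and an evenly spaced founder marker map. The
#' three default QTL positions of [default_qtl_model()] (the *GBSS1* site
#' chr6:1,769,686 and the minor sites on chr1 and chr11) are always included
#' as founder sites so that phenotype simulation can address them.
#'
#' Allele pairs are assigned deterministically (cycling through nucleotide
#' pairs by site index); the recurrent allele doubles as the reference.
#'
#' @param site_spacing approximate distance between founder sites, bp.
#' @param cm_per_mbp uniform genetic map rate, cM per Mbp.
#' @param extra_sites optional data.frame (`chrom`, `pos`) of positions to
#'   force into the map in addition to the evenly spaced grid.
#' @return A [genome_model()].
#' @export
rice_genome <- function(site_spacing = 250000, cm_per_mbp = 4.76,
                        extra_sites = NULL) {
  stopifnot(site_spacing > 0, cm_per_mbp > 0)
  chroms <- data.frame(
    name = paste0("chr", 1:12),
    length_bp = round(.rice_chrom_mbp * 1e6),
    length_cM = .rice_chrom_mbp * cm_per_mbp
  )
  qtl_pos <- data.frame(
    chrom = c("chr6", "chr1", "chr11"),
    pos = c(1769686L, 30038502L, 18288616L)
  )
  if (!is.null(extra_sites)) qtl_pos <- rbind(qtl_pos, extra_sites[c("chrom", "pos")])
  sites <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    cn <- chroms$name[i]
    grid <- seq(site_spacing, chroms$length_bp[i], by = site_spacing)
    pos <- sort(unique(c(grid, qtl_pos$pos[qtl_pos$chrom == cn])))
    data.frame(chrom = cn, pos = pos)
  }))
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  k <- (seq_len(nrow(sites)) - 1L) %% 4L + 1L
  sites$donor <- pairs[k, 1]
  sites$recurrent <- pairs[k, 2]
  genome_model(chroms, sites)
}

#' Genetic map rate of a chromosome (cM per Mbp)
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @return numeric rate.
#' @keywords internal
chrom_rate <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  genome$chromosomes$length_cM[i] / (genome$chromosomes$length_bp[i] / 1e6)
}
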