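# Pooled short-read sampling at founder sites.
#
# A pileup is a wide per-site read-count table for one cohort (a bulk or a
# parent): columns chrom, pos, sample, A, C, G, T, depth, phred. It stands
# in for mapped reads; no read-level simulation is done.

.nuc <- c("A", "C", "G", "T")
.other_alleles <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

# Scatter sequencing errors: reads from allele `src_idx` (per site) keep
# their base with prob 1 - error_rate, otherwise switch uniformly to one of
# the other three nucleotides. Returns an n x 4 count matrix increment.
.scatter_reads <- function(n_reads, src_idx, error_rate) {
  n <- length(n_reads)
  counts <- matrix(0L, nrow = n, ncol = 4L)
  keep <- stats::rbinom(n, n_reads, 1 - error_rate)
  err <- n_reads - keep
  e1 <- stats::rbinom(n, err, 1 / 3)
  e2 <- stats::rbinom(n, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  idx <- cbind(seq_len(n), src_idx)
  counts[idx] <- counts[idx] + keep
  oth <- .other_alleles[src_idx, , drop = FALSE]
  counts[cbind(seq_len(n), oth[, 1])] <- counts[cbind(seq_len(n), oth[, 1])] + e1
  counts[cbind(seq_len(n), oth[, 2])] <- counts[cbind(seq_len(n), oth[, 2])] + e2
  counts[cbind(seq_len(n), oth[, 3])] <- counts[cbind(seq_len(n), oth[, 3])] + e3
  counts
}

#' Simulate a pooled-sequencing pileup for a cohort
#'
#' Each member of the bulk contributes its two haplotypes in equal
#' proportion (equal-amount DNA pooling). Per site, total depth is
#' Poisson(`mean_depth`); each read draws a parental allele from the pooled
#' allele frequency and is miscalled with probability `error_rate`
#' (uniformly to one of the other three nucleotides). The site quality score
#' is a constant phred value, optionally degraded to `low_phred` for a
#' random fraction of sites to exercise downstream quality filtering.
#'
#' A parent cohort is simply a bulk of size one (the founder individual).
#'
#' @param bulk_members list of individuals (non-empty).
#' @param genome a [genome_model()].
#' @param mean_depth mean sequencing depth (> 0); e.g. 53 and 59 for the
#'   default high- and low-phenotype bulks.
#' @param error_rate per-read base miscall probability in [0, 0.25).
#' @param sample_id cohort label recorded in the `sample` column.
#' @param phred_score site quality score assigned to sites (default 40).
#' @param low_quality_fraction fraction of sites drawn at `low_phred`.
#' @param low_phred degraded site quality score.
#' @param sites optional subset of founder sites (data.frame `chrom`,`pos`);
#'   default all sites in the genome.
#' @param seed optional integer seed.
#' @return data.frame: `chrom`, `pos`, `sample`, `A`, `C`, `G`, `T`,
#'   `depth`, `phred`.
#' @export
simulate_bulk_pileup <- function(bulk_members, genome, mean_depth,
                                 error_rate = 0.001, sample_id = "bulk",
                                 phred_score = 40, low_quality_fraction = 0,
                                 low_phred = 20, sites = NULL, seed = NULL) {
  if (length(bulk_members) == 0) stop("empty bulk")
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.25)
  if (!is.null(seed)) set.seed(seed)
  smap <- genome$sites
  if (!is.null(sites)) {
    keep <- paste0(smap$chrom, ":", smap$pos) %in% paste0(sites$chrom, ":", sites$pos)
    smap <- smap[keep, , drop = FALSE]
  }
  n <- nrow(smap)
  dos <- genotype_dosage(bulk_members, genome)
  dos <- dos[, paste0(smap$chrom, ":", smap$pos), drop = FALSE]
  f_donor <- colMeans(dos) / 2
  depth <- stats::rpois(n, mean_depth)
  donor_reads <- stats::rbinom(n, depth, f_donor)
  rec_reads <- depth - donor_reads
  didx <- match(smap$donor, .nuc)
  ridx <- match(smap$recurrent, .nuc)
  counts <- .scatter_reads(donor_reads, didx, error_rate) +
            .scatter_reads(rec_reads, ridx, error_rate)
  phred <- rep(phred_score, n)
  if (low_quality_fraction > 0) {
    low <- stats::runif(n) < low_quality_fraction
    phred[low] <- low_phred
  }
  out <- data.frame(chrom = smap$chrom, pos = smap$pos, sample = sample_id,
                    counts[, 1], counts[, 2], counts[, 3], counts[, 4],
                    depth = rowSums(counts), phred = phred)
  names(out)[4:7] <- .nuc
  rownames(out) <- NULL
  out
}
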