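# Two-step candidate-marker identification: allele-frequency
# over-representation in the high bulk plus chi-square tests of the 1:1
# read-count null in both bulks, with coverage validation.

#' Chi-square test of a 1:1 read-count ratio
#'
#' For allele read counts (a, b) the statistic is (a - b)^2 / (a + b) with
#' one degree of freedom and no continuity correction; the P-value is the
#' upper tail of the chi-square distribution. This tests whether the two
#' parental alleles follow the binomial 1:1 segregation expected of
#' non-causative sites. Vectorised over `count_a`/`count_b`.
#'
#' @param count_a,count_b read counts of the two alleles.
#' @return data.frame with columns `statistic` and `p_value`; both are
#'   `NA` when `count_a + count_b == 0` (no test possible).
#' @examples
#' chisq_one_to_one(20, 0)   # statistic 20, P ~ 7.7e-6
#' @export
chisq_one_to_one <- function(count_a, count_b) {
  stopifnot(length(count_a) == length(count_b),
            all(count_a >= 0), all(count_b >= 0))
  n <- count_a + count_b
  stat <- ifelse(n > 0, (count_a - count_b)^2 / n, NA_real_)
  p <- ifelse(n > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), NA_real_)
  data.frame(statistic = stat, p_value = p)
}

#' Exact two-sided binomial test of a 1:1 ratio
#'
#' Oracle companion to [chisq_one_to_one()]: the exact two-sided binomial
#' P-value of `count_a` successes in `count_a + count_b` trials at p = 1/2
#' (via [stats::binom.test()]). Vectorised.
#'
#' @param count_a,count_b read counts of the two alleles.
#' @return numeric vector of P-values (`NA` where the total is zero).
#' @export
binom_one_to_one <- function(count_a, count_b) {
  mapply(function(a, b) {
    if (a + b == 0) return(NA_real_)
    stats::binom.test(a, a + b, p = 0.5)$p.value
  }, count_a, count_b)
}

#' Two-step classification of candidate markers
#'
#' A filtered site passes iff (i) the parental condition of step 1 (both
#' parents homozygous for different alleles) or step 2 (at least one parent
#' heterozygous but the two bulks fixed for different alleles) holds,
#' (ii) the donor-allele frequency in the high bulk reaches
#' `hab_freq_cutoff`, and (iii) the chi-square 1:1 test rejects at `alpha`
#' in both bulks, with (optionally) the required direction: the high bulk
#' skewed toward the donor allele and the low bulk toward the recurrent
#' allele. A site missing from a bulk's call set is still evaluated with
#' that bulk's raw pileup counts (a no-call is not zero reads).
#'
#' Frequencies reported for the cutoff are allele count / site depth, as in
#' coverage-based allele-frequency screening; the chi-square compares the
#' donor vs recurrent read counts only.
#'
#' @param candidates data.frame of filtered sites with columns `chrom`,
#'   `pos` (e.g. the union of bulk-specific calls after [filter_cascade()]).
#' @param hab_pileup,lab_pileup bulk pileups (raw counts per site).
#' @param parent1_geno,parent2_geno parent genotypes
#'   ([genotype_parents()]); parent 1 is the donor.
#' @param site_alleles data.frame `chrom`, `pos`, `donor`, `recurrent`
#'   naming the two parental alleles per site (a [genome_model()] is also
#'   accepted).
#' @param alpha per-bulk significance level (default 0.05, no
#'   multiple-testing correction).
#' @param hab_freq_cutoff minimum donor-allele frequency in the high bulk
#'   (default 0.90).
#' @param require_direction require the high bulk to skew toward the donor
#'   allele and the low bulk toward the recurrent allele (default TRUE).
#' @param fixation_freq allele frequency at which a bulk counts as "fixed"
#'   for the step-2 condition (default 0.90).
#' @return data.frame sorted by chromosome and position with per-bulk
#'   donor/recurrent counts, frequencies, chi-square statistics and
#'   P-values, exact binomial P-values, coverage, `step` (1, 2 or `NA`)
#'   and the `pass` flag.
#' @export
classify_candidates <- function(candidates, hab_pileup, lab_pileup,
                                parent1_geno, parent2_geno, site_alleles,
                                alpha = 0.05, hab_freq_cutoff = 0.90,
                                require_direction = TRUE,
                                fixation_freq = 0.90) {
  if (inherits(site_alleles, "genome_model")) site_alleles <- site_alleles$sites
  empty <- data.frame(chrom = character(), pos = integer())
  if (nrow(candidates) == 0) return(cbind(empty))
  key <- unique(paste0(candidates$chrom, ":", candidates$pos))
  sa_key <- paste0(site_alleles$chrom, ":", site_alleles$pos)
  sa <- site_alleles[match(key, sa_key), , drop = FALSE]
  if (anyNA(sa$donor)) stop("candidate site(s) missing from `site_alleles`")

  count_of <- function(pileup, alleles) {
    pk <- paste0(pileup$chrom, ":", pileup$pos)
    i <- match(key, pk)
    cm <- as.matrix(pileup[i, c("A", "C", "G", "T"), drop = FALSE])
    cbind(cm[cbind(seq_along(key), match(alleles$donor, colnames(cm)))],
          cm[cbind(seq_along(key), match(alleles$recurrent, colnames(cm)))],
          rowSums(cm))
  }
  hc <- count_of(hab_pileup, sa)
  lc <- count_of(lab_pileup, sa)
  if (anyNA(hc) || anyNA(lc)) stop("candidate site(s) missing from a bulk pileup")

  hab_freq <- ifelse(hc[, 3] > 0, hc[, 1] / hc[, 3], 0)
  lab_freq <- ifelse(lc[, 3] > 0, lc[, 1] / lc[, 3], 0)
  hab_test <- chisq_one_to_one(hc[, 1], hc[, 2])
  lab_test <- chisq_one_to_one(lc[, 1], lc[, 2])
  hab_binom <- binom_one_to_one(hc[, 1], hc[, 2])
  lab_binom <- binom_one_to_one(lc[, 1], lc[, 2])

  p1 <- parent1_geno[match(key, paste0(parent1_geno$chrom, ":", parent1_geno$pos)), ]
  p2 <- parent2_geno[match(key, paste0(parent2_geno$chrom, ":", parent2_geno$pos)), ]
  both_hom_diff <- !is.na(p1$class) & !is.na(p2$class) &
    p1$class == "hom" & p2$class == "hom" & p1$allele1 != p2$allele1
  any_het <- (!is.na(p1$class) & p1$class == "het") |
             (!is.na(p2$class) & p2$class == "het")
  # step 2: bulks fixed for different alleles
  hab_major_frac <- ifelse(hc[, 3] > 0, pmax(hc[, 1], hc[, 2]) / hc[, 3], 0)
  lab_major_frac <- ifelse(lc[, 3] > 0, pmax(lc[, 1], lc[, 2]) / lc[, 3], 0)
  hab_major_donor <- hc[, 1] >= hc[, 2]
  lab_major_donor <- lc[, 1] >= lc[, 2]
  bulks_fixed_diff <- hab_major_frac >= fixation_freq &
    lab_major_frac >= fixation_freq & (hab_major_donor != lab_major_donor)
  step <- ifelse(both_hom_diff, 1L, ifelse(any_het & bulks_fixed_diff, 2L, NA_integer_))

  direction_ok <- if (require_direction) {
    hab_freq > 0.5 & lab_freq < 0.5
  } else TRUE
  pass <- !is.na(step) &
    hab_freq >= hab_freq_cutoff &
    !is.na(hab_test$p_value) & hab_test$p_value < alpha &
    !is.na(lab_test$p_value) & lab_test$p_value < alpha &
    direction_ok

  out <- data.frame(
    chrom = sa$chrom, pos = sa$pos,
    hab_donor = hc[, 1], hab_recurrent = hc[, 2], hab_depth = hc[, 3],
    lab_donor = lc[, 1], lab_recurrent = lc[, 2], lab_depth = lc[, 3],
    hab_freq = hab_freq, lab_freq = lab_freq,
    hab_chisq = hab_test$statistic, hab_p = hab_test$p_value,
    lab_chisq = lab_test$statistic, lab_p = lab_test$p_value,
    hab_binom_p = hab_binom, lab_binom_p = lab_binom,
    step = step, pass = pass
  )
  out <- out[order(match(out$chrom, unique(site_alleles$chrom)), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Coverage validation of candidate markers
#'
#' Annotates each candidate with its minimum and maximum coverage across
#' the two bulks and flags candidates whose coverage falls below
#' `expected_min` as low-confidence: low coverage causes sampling error
#' that can produce spurious deviations from the 50% segregation pattern.
#'
#' @param results output of [classify_candidates()].
#' @param expected_min minimum acceptable per-bulk coverage (default 20).
#' @return `results` with added columns `cov_min`, `cov_max` and
#'   `low_confidence`.
#' @export
coverage_report <- function(results, expected_min = 20) {
  if (nrow(results) == 0) {
    results$cov_min <- numeric(0)
    results$cov_max <- numeric(0)
    results$low_confidence <- logical(0)
    return(results)
  }
  results$cov_min <- pmin(results$hab_depth, results$lab_depth)
  results$cov_max <- pmax(results$hab_depth, results$lab_depth)
  results$low_confidence <- results$cov_min < expected_min
  results
}

#' Null parental read fraction in pooled sequencing
#'
#' Monte-Carlo estimate of the mean donor-read fraction at loci with no
#' genetic effect on the trait. By default each site's pooled donor-allele
#' frequency arises from an equal-contribution bulk whose 2 x `bulk_size`
#' haplotypes carry the donor allele independently with probability
#' `donor_freq` (0.5 for an F2-derived population); read depths are
#' Poisson(`mean_depth`) and reads are drawn binomially from the pooled
#' frequency, with optional base errors. Supplying `freqs` overrides the
#' haplotype sampling with externally computed pooled frequencies (e.g.
#' from a backcross population, whose expected fraction is (1/2)^(1+b),
#' 12.5% for two backcrosses, not 50%).
#'
#' @param n_sites number of unlinked sites.
#' @param bulk_size individuals per bulk.
#' @param mean_depth mean read depth per site.
#' @param donor_freq population donor-allele frequency at unlinked loci.
#' @param error_rate per-read miscall probability (an erroneous read is
#'   counted for neither parent with probability 2/3, for the other parent
#'   with probability 1/3).
#' @param freqs optional numeric vector of pooled donor frequencies per
#'   site (recycled to `n_sites`); bypasses haplotype sampling.
#' @param seed optional integer seed.
#' @return list(`mean_fraction`, `mc_se`, `n_sites`, `fractions`).
#' @export
null_allele_fraction <- function(n_sites = 1000, bulk_size = 10,
                                 mean_depth = 50, donor_freq = 0.5,
                                 error_rate = 0, freqs = NULL, seed = NULL) {
  stopifnot(n_sites >= 1, bulk_size >= 1, mean_depth > 0,
            donor_freq >= 0, donor_freq <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) {
    n_hap <- 2 * bulk_size
    freqs <- stats::rbinom(n_sites, n_hap, donor_freq) / n_hap
  } else {
    freqs <- rep_len(freqs, n_sites)
  }
  depth <- stats::rpois(n_sites, mean_depth)
  donor_reads <- stats::rbinom(n_sites, depth, freqs)
  rec_reads <- depth - donor_reads
  if (error_rate > 0) {
    keep_d <- stats::rbinom(n_sites, donor_reads, 1 - error_rate)
    keep_r <- stats::rbinom(n_sites, rec_reads, 1 - error_rate)
    d2r <- stats::rbinom(n_sites, donor_reads - keep_d, 1 / 3)
    r2d <- stats::rbinom(n_sites, rec_reads - keep_r, 1 / 3)
    donor_reads <- keep_d + r2d
    rec_reads <- keep_r + d2r
  }
  total <- donor_reads + rec_reads
  frac <- ifelse(total > 0, donor_reads / total, NA_real_)
  frac_ok <- frac[!is.na(frac)]
  list(mean_fraction = mean(frac_ok),
       mc_se = stats::sd(frac_ok) / sqrt(length(frac_ok)),
       n_sites = n_sites, fractions = frac)
}
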