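test_that("the 1:1 chi-square statistic and tail are exact", {
  expect_equal(chisq_one_to_one(10, 10), data.frame(statistic = 0, p_value = 1))
  r <- chisq_one_to_one(20, 0)
  expect_equal(r$statistic, 20)
  expect_equal(r$p_value, 7.744216e-06, tolerance = 1e-6)
  r2 <- chisq_one_to_one(15, 5)
  expect_equal(r2$statistic, 5)
  expect_equal(r2$p_value, 0.02534732, tolerance = 1e-6)
  # vectorised; zero totals yield the no-test marker
  v <- chisq_one_to_one(c(3, 0), c(3, 0))
  expect_equal(v$statistic, c(0, NA))
  expect_true(is.na(v$p_value[2]))
})

test_that("chi-square and exact binomial decisions disagree only on the frozen boundary set", {
  frozen <- utils::read.csv(test_path("fixtures", "chisq-binom-disagreement.csv"))
  got <- list()
  for (n in 1:60) {
    a <- 0:n
    pc <- chisq_one_to_one(a, n - a)$p_value
    pb <- binom_one_to_one(a, n - a)
    dis <- which((pc < 0.05) != (pb < 0.05))
    if (length(dis) > 0) {
      got[[length(got) + 1]] <- data.frame(a = a[dis], b = n - a[dis])
    }
  }
  got <- do.call(rbind, got)
  expect_equal(nrow(got), nrow(frozen))
  expect_setequal(paste(got$a, got$b), paste(frozen$a, frozen$b))
  # in every disagreement the chi-square is the anti-conservative side
  i <- match(paste(frozen$a, frozen$b), paste(got$a, got$b))
  expect_true(all(frozen$chisq_p < 0.05 & frozen$binom_p >= 0.05))
})

test_that("two-step candidate classification applies every condition", {
  sites <- data.frame(chrom = "c1", pos = c(100, 200, 300),
                      donor = "A", recurrent = "G")
  hab <- rbind(make_pileup("c1", 100, A = 50, sample = "HAB"),
               make_pileup("c1", 200, A = 25, G = 25, sample = "HAB"),
               make_pileup("c1", 300, A = 46, G = 4, sample = "HAB"))
  lab <- rbind(make_pileup("c1", 100, G = 50, sample = "LAB"),
               make_pileup("c1", 200, A = 25, G = 25, sample = "LAB"),
               make_pileup("c1", 300, A = 5, G = 45, sample = "LAB"))
  p1 <- make_parent_geno("c1", c(100, 200, 300), "hom", "A")
  p2 <- make_parent_geno("c1", c(100, 200, 300), "hom", "G")
  res <- classify_candidates(data.frame(chrom = "c1", pos = c(100, 200, 300)),
                             hab, lab, p1, p2, sites)
  # maximal divergence: passes as step 1
  expect_true(res$pass[res$pos == 100])
  expect_equal(res$step[res$pos == 100], 1L)
  # 50% frequency: fails regardless of the other bulk
  expect_false(res$pass[res$pos == 200])
  # 92% vs 10%: chi-square 35.28 in both bulks, passes
  r3 <- res[res$pos == 300, ]
  expect_true(r3$pass)
  expect_equal(r3$hab_chisq, 35.28)
  expect_equal(r3$lab_chisq, 32)
  expect_lt(r3$hab_p, 0.05)
  expect_lt(r3$lab_p, 0.05)
  expect_equal(r3$hab_freq, 0.92)
})

test_that("step 2 requires a heterozygous parent and oppositely fixed bulks", {
  sites <- data.frame(chrom = "c1", pos = 1:2, donor = "A", recurrent = "G")
  hab <- rbind(make_pileup("c1", 1, A = 48, G = 2, sample = "HAB"),
               make_pileup("c1", 2, A = 30, G = 20, sample = "HAB"))
  lab <- rbind(make_pileup("c1", 1, G = 50, sample = "LAB"),
               make_pileup("c1", 2, G = 50, sample = "LAB"))
  p1 <- make_parent_geno("c1", 1:2, "het", "A", "G")
  p2 <- make_parent_geno("c1", 1:2, "hom", "G")
  res <- classify_candidates(data.frame(chrom = "c1", pos = 1:2),
                             hab, lab, p1, p2, sites)
  expect_equal(res$step[res$pos == 1], 2L)
  expect_true(res$pass[res$pos == 1])
  expect_true(is.na(res$step[res$pos == 2]))  # high bulk not fixed
  expect_false(res$pass[res$pos == 2])
})

test_that("direction and threshold changes are monotone in the candidate set", {
  set.seed(61)
  g <- toy_genome(n_chrom = 2, len_bp = 4e6, len_cM = 60, n_sites = 30)
  pop <- breed_bc2f8(g, 60, seed = 62)
  hab <- simulate_bulk_pileup(pop[1:10], g, 53, 0.01, sample_id = "HAB", seed = 63)
  lab <- simulate_bulk_pileup(pop[11:20], g, 59, 0.01, sample_id = "LAB", seed = 64)
  p1g <- make_parent_geno(g$sites$chrom, g$sites$pos, "hom", g$sites$donor)
  p2g <- make_parent_geno(g$sites$chrom, g$sites$pos, "hom", g$sites$recurrent)
  cand <- g$sites[, c("chrom", "pos")]
  base <- classify_candidates(cand, hab, lab, p1g, p2g, g,
                              alpha = 0.5, hab_freq_cutoff = 0.3)
  key <- function(r) paste0(r$chrom, ":", r$pos)[r$pass]
  stricter_freq <- classify_candidates(cand, hab, lab, p1g, p2g, g,
                                       alpha = 0.5, hab_freq_cutoff = 0.6)
  stricter_alpha <- classify_candidates(cand, hab, lab, p1g, p2g, g,
                                        alpha = 0.01, hab_freq_cutoff = 0.3)
  expect_true(all(key(stricter_freq) %in% key(base)))
  expect_true(all(key(stricter_alpha) %in% key(base)))
  no_dir <- classify_candidates(cand, hab, lab, p1g, p2g, g,
                                alpha = 0.5, hab_freq_cutoff = 0.3,
                                require_direction = FALSE)
  expect_true(all(key(base) %in% key(no_dir)))
})

test_that("coverage validation flags candidates below the expected minimum", {
  res <- data.frame(chrom = "c1", pos = 1:2,
                    hab_depth = c(21, 12), lab_depth = c(41, 30))
  out <- coverage_report(res, expected_min = 20)
  expect_equal(out$cov_min, c(21, 12))
  expect_equal(out$cov_max, c(41, 30))
  expect_equal(out$low_confidence, c(FALSE, TRUE))
  empty <- coverage_report(res[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("cov_min", "cov_max", "low_confidence") %in% names(empty)))
})

test_that("the null read fraction is 50% for equal parental contribution", {
  nf <- null_allele_fraction(n_sites = 1000, bulk_size = 10, mean_depth = 50,
                             donor_freq = 0.5, seed = 71)
  expect_lt(abs(nf$mean_fraction - 0.5), 0.01)
  # fixed pooled donor frequency 1: every read is donor
  nf1 <- null_allele_fraction(n_sites = 50, mean_depth = 50, freqs = 1, seed = 72)
  expect_equal(nf1$mean_fraction, 1)
})

test_that("a two-backcross population shifts the null fraction to 12.5%", {
  g <- toy_genome(n_chrom = 4, len_bp = 2e7, len_cM = 95, n_sites = 40)
  pop <- breed_bc2f8(g, 150, seed = 73)
  pooled <- colMeans(genotype_dosage(pop, g)) / 2
  nf <- null_allele_fraction(n_sites = length(pooled), mean_depth = 50,
                             freqs = pooled, seed = 74)
  expect_lt(abs(nf$mean_fraction - 0.125), 0.02)
})

test_that("passing sites are specific to the QTL-bearing chromosome", {
  cfg <- bsa_config(qtl_chrom = "chr6", qtl_pos = 1769686L, qtl_effect = 2.5)
  causal_freq <- c()
  for (s in 1:5) {
    res <- run_bsa_pipeline(cfg, seed = s)
    off <- res$candidates[res$candidates$chrom != "chr6", ]
    expect_equal(nrow(off), 0)
    hab <- res$pileups$HAB
    i <- which(hab$chrom == "chr6" & hab$pos == 1769686)
    don <- res$genome$sites$donor[i]
    causal_freq <- c(causal_freq, hab[i, don] / hab$depth[i])
  }
  # the high bulk is strongly enriched for the donor allele at the causal
  # site (population-wide expectation is 12.5%)
  expect_gt(mean(causal_freq), 0.5)
})
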