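test_that("single-site calling enforces the three thresholds", {
  bp <- bulk_call_params()
  # depth 25, alt 24 (96%): all thresholds met
  expect_equal(call_site(c(A = 1, G = 24), "A", bp)$allele, "G")
  # depth 19, alt 19 (100%): coverage below 20
  expect_null(call_site(c(G = 19), "A", bp))
  # allele-mining parameters 20/8/30%: depth 20, alt 8 (40%) is called
  expect_equal(call_site(c(A = 12, T = 8), "A", mining_call_params())$allele, "T")
  # count threshold binds even at high coverage
  expect_null(call_site(c(A = 80, G = 19), "A", bulk_call_params()))
  # zero depth is a no-call, not an error
  expect_null(call_site(c(A = 0), "A", bp))
  expect_error(call_site(c(A = -1), "A", bp), "negative")
})

test_that("calling agrees with a brute-force re-check of the inequalities", {
  set.seed(31)
  params <- call_params(20, 8, 0.3)
  for (i in 1:1000) {
    counts <- stats::rpois(4, sample(c(0.5, 3, 10), 4, replace = TRUE))
    names(counts) <- c("A", "C", "G", "T")
    ref <- sample(names(counts), 1)
    got <- call_site(counts, ref, params)
    # independent oracle: scan every non-reference allele
    depth <- sum(counts)
    called <- NULL
    for (a in setdiff(names(counts), ref)) {
      if (depth >= 20 && counts[[a]] >= 8 && counts[[a]] / depth >= 0.3) {
        if (is.null(called) || counts[[a]] > counts[[called]]) called <- a
      }
    }
    if (is.null(called)) {
      expect_null(got)
    } else {
      expect_equal(got$allele, called)
      expect_equal(got$count, counts[[called]])
      expect_equal(got$freq, counts[[called]] / depth)
    }
  }
})

test_that("table-level calling matches site-level calling", {
  set.seed(32)
  g <- toy_genome(n_chrom = 1, len_bp = 1e6, len_cM = 50, n_sites = 60)
  pop <- breed_bc2f8(g, 12, seed = 33)
  p <- simulate_bulk_pileup(pop, g, 25, error_rate = 0.02, seed = 34)
  calls <- call_variants(p, g, mining_call_params())
  for (i in seq_len(nrow(p))) {
    cs <- call_site(unlist(p[i, c("A", "C", "G", "T")]),
                    g$sites$recurrent[i], mining_call_params())
    in_calls <- any(calls$pos == p$pos[i])
    expect_equal(!is.null(cs), in_calls)
    if (!is.null(cs)) {
      expect_equal(calls$allele[calls$pos == p$pos[i]], cs$allele)
    }
  }
})

test_that("two-way bulk comparison keeps only bulk-specific SNPs", {
  mk <- function(pos, allele) data.frame(chrom = "c1", pos = pos, sample = "x",
                                         allele = allele, count = 20, depth = 20,
                                         freq = 1, phred = 40)
  hab <- mk(c(100, 200), c("A", "C"))
  lab <- mk(c(200, 300), c("C", "T"))
  sh <- filter_shared(hab, lab)
  expect_equal(sh$hab_only$pos, 100)
  expect_equal(sh$lab_only$pos, 300)

  ident <- filter_shared(hab, hab)
  expect_equal(nrow(ident$hab_only), 0)
  expect_equal(nrow(ident$lab_only), 0)

  disj <- filter_shared(mk(1, "A"), mk(2, "A"))
  expect_equal(disj$hab_only$pos, 1)
  expect_equal(disj$lab_only$pos, 2)

  # zero-row inputs must yield zero-row outputs (regression: paste0 recycling)
  none <- filter_shared(hab[0, ], lab)
  expect_equal(nrow(none$hab_only), 0)
  expect_equal(nrow(none$lab_only), nrow(lab))
})

test_that("the phred filter removes scores strictly below the threshold", {
  mk <- function(phred) data.frame(chrom = "c1", pos = seq_along(phred),
                                   sample = "x", allele = "A", count = 20,
                                   depth = 20, freq = 1, phred = phred)
  out <- filter_quality(mk(c(29.9, 30, 35)))
  expect_equal(out$phred, c(30, 35))  # exactly 30 survives: "<30" is removed
  expect_equal(nrow(filter_quality(mk(35)[0, ])), 0)
  expect_message(out2 <- filter_quality(mk(c(NA, 40))), "missing phred")
  expect_equal(out2$phred, 40)
})

test_that("multi-allelic and non-parental positions are excluded", {
  calls <- data.frame(chrom = "c1", pos = c(10, 20, 30), sample = "HAB",
                      allele = c("T", "A", "A"), count = 20, depth = 20,
                      freq = 1, phred = 40)
  # site 10: bulk allele T but parents A/G -> non-parental
  # site 20: three alleles with >= 2 reads across cohorts -> multi-allelic
  # site 30: biallelic, allele matches the donor parent -> kept
  pile <- rbind(
    make_pileup("c1", 10, A = 10, G = 10, T = 20, sample = "HAB"),
    make_pileup("c1", 20, A = 20, G = 3, T = 2, sample = "HAB"),
    make_pileup("c1", 30, A = 20, G = 1, sample = "HAB"))
  p1 <- make_parent_geno("c1", c(10, 20, 30), "hom", "A")
  p2 <- make_parent_geno("c1", c(10, 20, 30), "hom", "G")
  out <- filter_biallelic_parental(calls, p1, p2, list(pile))
  expect_equal(out$pos, 30)

  # a parental no-call drops the position and is counted
  p1b <- p1; p1b$class[3] <- "nocall"; p1b$allele1[3] <- NA
  out2 <- filter_biallelic_parental(calls, p1b, p2, list(pile))
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped_nocall"), 1L)
})

test_that("parent genotyping distinguishes hom, het and no-call", {
  g <- data.frame(chrom = "c1", pos = c(1, 2, 3, 4), ref = "G")
  pile <- rbind(make_pileup("c1", 1, A = 10),            # hom alt
                make_pileup("c1", 2, G = 8),             # hom ref
                make_pileup("c1", 3, A = 5, G = 5),      # het (each < 100%)
                make_pileup("c1", 4, A = 2))             # coverage below 5
  gt <- genotype_parents(pile, g)
  expect_equal(gt$class, c("hom", "hom", "het", "nocall"))
  expect_equal(gt$allele1[1:3], c("A", "G", "A"))
  expect_equal(gt$allele2[3], "G")
})

test_that("the cascade is monotone and idempotent", {
  g <- toy_genome(n_chrom = 2, len_bp = 4e6, len_cM = 60, n_sites = 40)
  pop <- breed_bc2f8(g, 40, seed = 51)
  hab <- simulate_bulk_pileup(pop[1:10], g, 53, 0.005, sample_id = "HAB", seed = 52)
  lab <- simulate_bulk_pileup(pop[11:20], g, 59, 0.005, sample_id = "LAB", seed = 53)
  pd <- simulate_bulk_pileup(list(founder_individual(g, "donor")), g, 30,
                             0.005, sample_id = "P1", seed = 54)
  pr <- simulate_bulk_pileup(list(founder_individual(g, "recurrent")), g, 30,
                             0.005, sample_id = "P2", seed = 55)
  f <- filter_cascade(hab, lab, pd, pr, g)
  # monotone: per-cohort counts never grow along the cascade
  for (cohort in c("HAB", "LAB")) {
    n <- f$log$n[f$log$cohort == cohort]
    expect_true(all(diff(n) <= 0))
  }
  # each surviving call was present in the initial call set
  hab0 <- call_variants(hab, g, bulk_call_params())
  expect_true(all(paste0(f$hab$pos, f$hab$allele) %in%
                  paste0(hab0$pos, hab0$allele)))
  # idempotent: re-running the downstream filters on the survivors is a no-op
  sh2 <- filter_shared(f$hab, f$lab)
  expect_equal(sh2$hab_only[, 1:8], f$hab[, 1:8], ignore_attr = TRUE)
  q2 <- filter_quality(f$hab)
  expect_equal(q2, f$hab[, 1:8], ignore_attr = TRUE)
  b2 <- filter_biallelic_parental(f$hab, f$parent1_geno, f$parent2_geno,
                                  list(hab, lab, pd, pr))
  expect_equal(b2$pos, f$hab$pos)
})

test_that("ideal fixed-difference sites are always called at full depth", {
  # error-free reads, fixed bulks, depth >= 20: no false negatives
  g <- toy_genome(n_chrom = 1, len_bp = 1e6, len_cM = 40, n_sites = 30)
  donors <- replicate(10, founder_individual(g, "donor"), simplify = FALSE)
  p <- simulate_bulk_pileup(donors, g, 60, error_rate = 0, seed = 56)
  p <- p[p$depth >= 20, ]
  calls <- call_variants(p, g, bulk_call_params())
  expect_equal(nrow(calls), nrow(p))
  expect_true(all(calls$allele == "A"))
})
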