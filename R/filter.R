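# Threshold-based SNP calling and the filtering cascade:
# call -> remove SNPs shared by both bulks -> site-quality (phred) filter ->
# multi-allelic / non-parental exclusion.

#' Variant-calling threshold parameters
#'
#' The three thresholds of basic (frequency-based) variant detection:
#' minimum site coverage, minimum reads supporting the called allele, and
#' minimum allele frequency (count/depth).
#'
#' Presets: [bulk_call_params()] (20 / 20 / 90%, used for the bulks),
#' [parent_call_params()] (5 / 5 / 100%, used for the parents) and
#' [mining_call_params()] (20 / 8 / 30%, used for allele mining in
#' unrelated accessions).
#'
#' @param min_coverage minimum total depth at the site.
#' @param min_count minimum reads supporting the called allele.
#' @param min_freq minimum allele frequency, in (0, 1].
#' @return An object of class `call_params`.
#' @export
call_params <- function(min_coverage, min_count, min_freq) {
  stopifnot(min_coverage >= min_count, min_count >= 0,
            min_freq > 0, min_freq <= 1)
  structure(list(min_coverage = min_coverage, min_count = min_count,
                 min_freq = min_freq), class = "call_params")
}

#' @rdname call_params
#' @export
bulk_call_params <- function() call_params(20, 20, 0.90)

#' @rdname call_params
#' @export
parent_call_params <- function() call_params(5, 5, 1.00)

#' @rdname call_params
#' @export
mining_call_params <- function() call_params(20, 8, 0.30)

#' Call a variant at a single site
#'
#' The non-reference allele with the highest read count is called iff
#' depth >= min_coverage, its count >= min_count and its frequency
#' (count/depth) >= min_freq. Zero depth is a no-call, not an error.
#'
#' @param counts named numeric vector of read counts for alleles
#'   A, C, G, T (missing names treated as 0).
#' @param ref_allele the reference allele at the site.
#' @param params a [call_params()].
#' @param phred site quality score (carried through).
#' @param chrom,pos,sample identifiers carried into the output row.
#' @return A one-row data.frame (`chrom`, `pos`, `sample`, `allele`,
#'   `count`, `depth`, `freq`, `phred`) or `NULL` for a no-call.
#' @export
call_site <- function(counts, ref_allele, params, phred = NA_real_,
                      chrom = NA_character_, pos = NA_integer_,
                      sample = NA_character_) {
  cc <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  cc[names(counts)] <- counts
  if (any(cc < 0)) stop("negative read count")
  depth <- sum(cc)
  if (depth == 0) return(NULL)
  alt <- cc[setdiff(names(cc), ref_allele)]
  allele <- names(alt)[which.max(alt)]
  count <- alt[[allele]]
  if (depth >= params$min_coverage && count >= params$min_count &&
      count / depth >= params$min_freq) {
    data.frame(chrom = chrom, pos = pos, sample = sample, allele = allele,
               count = count, depth = depth, freq = count / depth,
               phred = phred)
  } else {
    NULL
  }
}

.empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), sample = character(),
             allele = character(), count = numeric(), depth = numeric(),
             freq = numeric(), phred = numeric())
}

#' Call variants across a pileup table
#'
#' Vectorised application of [call_site()] to every site of a cohort
#' pileup, against the reference alleles of the genome (the recurrent
#' parent in synthetic mode).
#'
#' @param pileup cohort pileup (see [simulate_bulk_pileup()]).
#' @param ref data.frame with columns `chrom`, `pos`, `ref` giving the
#'   reference allele per site, or a [genome_model()] (whose recurrent
#'   alleles are used).
#' @param params a [call_params()].
#' @return data.frame of variant calls (possibly zero rows) with columns
#'   `chrom`, `pos`, `sample`, `allele`, `count`, `depth`, `freq`, `phred`.
#' @export
call_variants <- function(pileup, ref, params) {
  if (inherits(ref, "genome_model")) {
    ref <- data.frame(chrom = ref$sites$chrom, pos = ref$sites$pos,
                      ref = ref$sites$recurrent)
  }
  key <- paste0(pileup$chrom, ":", pileup$pos)
  rkey <- paste0(ref$chrom, ":", ref$pos)
  ridx <- match(key, rkey)
  if (anyNA(ridx)) stop("pileup site(s) missing from the reference table")
  refallele <- ref$ref[ridx]
  cm <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(cm)
  # mask the reference column, then take the best remaining allele
  cm_alt <- cm
  cm_alt[cbind(seq_len(nrow(cm)), match(refallele, c("A", "C", "G", "T")))] <- -1
  best <- max.col(cm_alt, ties.method = "first")
  count <- cm[cbind(seq_len(nrow(cm)), best)]
  freq <- ifelse(depth > 0, count / depth, 0)
  ok <- depth > 0 & depth >= params$min_coverage & count >= params$min_count &
        freq >= params$min_freq
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos,
                    sample = pileup$sample,
                    allele = c("A", "C", "G", "T")[best],
                    count = count, depth = depth, freq = freq,
                    phred = pileup$phred)[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.call_key <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  paste0(calls$chrom, ":", calls$pos, ":", calls$allele)
}

#' Remove SNPs present in both bulks
#'
#' Two-way comparison of the bulk call sets keyed by (chromosome,
#' position, allele); calls present in both are filtered out, leaving the
#' bulk-specific differences in both directions.
#'
#' @param hab_calls,lab_calls call tables (see [call_variants()]).
#' @return list(`hab_only`, `lab_only`).
#' @export
filter_shared <- function(hab_calls, lab_calls) {
  hk <- .call_key(hab_calls)
  lk <- .call_key(lab_calls)
  list(hab_only = hab_calls[!(hk %in% lk), , drop = FALSE],
       lab_only = lab_calls[!(lk %in% hk), , drop = FALSE])
}

#' Site-quality (phred) filter
#'
#' Keeps calls with phred >= `min_phred`; scores strictly below the
#' threshold are removed, so a call at exactly the threshold survives.
#' Calls with missing phred fail the filter (provenance cannot be
#' verified); their number is reported via a message.
#'
#' @param calls call table.
#' @param min_phred quality threshold (default 30).
#' @return Filtered call table, original order preserved.
#' @export
filter_quality <- function(calls, min_phred = 30) {
  if (nrow(calls) == 0) return(calls)
  missing <- is.na(calls$phred)
  if (any(missing)) {
    message(sum(missing), " call(s) with missing phred removed")
  }
  out <- calls[!missing & calls$phred >= min_phred, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype the parents from their pileups
#'
#' A parent is called homozygous for its top allele when that allele's
#' frequency reaches `params$min_freq` (100% by default, so a parent
#' showing two alleles can never be homozygous). A site with adequate
#' coverage whose top allele falls short of `min_freq` but where two
#' alleles each have >= `min_allele_reads` supporting reads is recorded as
#' heterozygous (used by association step 2 rather than discarded);
#' anything else is a no-call.
#'
#' @param pileup parent pileup.
#' @param ref reference table or [genome_model()] (as in [call_variants()]).
#' @param params a [call_params()] (default [parent_call_params()]).
#' @param min_allele_reads read floor for the heterozygote's second allele.
#' @return data.frame: `chrom`, `pos`, `class` (one of `"hom"`, `"het"`,
#'   `"nocall"`), `allele1`, `allele2` (`NA` unless het).
#' @export
genotype_parents <- function(pileup, ref, params = parent_call_params(),
                             min_allele_reads = 2) {
  if (inherits(ref, "genome_model")) {
    ref <- data.frame(chrom = ref$sites$chrom, pos = ref$sites$pos,
                      ref = ref$sites$recurrent)
  }
  cm <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(cm)
  ord1 <- max.col(cm, ties.method = "first")
  top <- cm[cbind(seq_len(nrow(cm)), ord1)]
  cm2 <- cm
  cm2[cbind(seq_len(nrow(cm)), ord1)] <- -1
  ord2 <- max.col(cm2, ties.method = "first")
  second <- cm[cbind(seq_len(nrow(cm)), ord2)]
  cls <- rep("nocall", nrow(cm))
  a1 <- c("A", "C", "G", "T")[ord1]
  a2 <- rep(NA_character_, nrow(cm))
  hom <- depth >= params$min_coverage & top >= params$min_count &
         ifelse(depth > 0, top / depth, 0) >= params$min_freq
  het <- !hom & depth >= params$min_coverage &
         top >= min_allele_reads & second >= min_allele_reads &
         ifelse(depth > 0, top / depth, 0) < params$min_freq
  cls[hom] <- "hom"
  cls[het] <- "het"
  a1[cls == "nocall"] <- NA_character_
  a2[het] <- c("A", "C", "G", "T")[ord2[het]]
  data.frame(chrom = pileup$chrom, pos = pileup$pos, class = cls,
             allele1 = a1, allele2 = a2)
}

#' Exclude multi-allelic and non-parental positions
#'
#' Removes (i) positions where more than two alleles are observed above
#' noise -- i.e. at least three alleles each supported by
#' >= `min_allele_reads` reads, summed across all cohort pileups -- and
#' (ii) positions whose called bulk allele is absent from both parents'
#' genotypes. Positions where either parent is a no-call are dropped and
#' counted (allele provenance cannot be verified).
#'
#' @param calls bulk call table to filter.
#' @param parent1_geno,parent2_geno parent genotype tables
#'   (see [genotype_parents()]).
#' @param cohort_pileups list of pileup data.frames (bulks and parents)
#'   used for the multi-allelic check.
#' @param min_allele_reads per-allele read floor defining "observed above
#'   noise" (default 2).
#' @return Filtered call table; attribute `"n_dropped_nocall"` records how
#'   many calls were lost to parental no-calls.
#' @export
filter_biallelic_parental <- function(calls, parent1_geno, parent2_geno,
                                      cohort_pileups, min_allele_reads = 2) {
  if (nrow(calls) == 0) {
    attr(calls, "n_dropped_nocall") <- 0L
    return(calls)
  }
  pool <- do.call(rbind, lapply(cohort_pileups, function(p) {
    p[, c("chrom", "pos", "A", "C", "G", "T")]
  }))
  agg <- stats::aggregate(pool[, c("A", "C", "G", "T")],
                          by = list(chrom = pool$chrom, pos = pool$pos), FUN = sum)
  n_alleles <- rowSums(as.matrix(agg[, c("A", "C", "G", "T")]) >= min_allele_reads)
  multi_key <- paste0(agg$chrom, ":", agg$pos)[n_alleles > 2]

  site_key <- paste0(calls$chrom, ":", calls$pos)
  keep <- !(site_key %in% multi_key)

  pg_key1 <- paste0(parent1_geno$chrom, ":", parent1_geno$pos)
  pg_key2 <- paste0(parent2_geno$chrom, ":", parent2_geno$pos)
  i1 <- match(site_key, pg_key1)
  i2 <- match(site_key, pg_key2)
  cls1 <- parent1_geno$class[i1]
  cls2 <- parent2_geno$class[i2]
  nocall <- is.na(cls1) | is.na(cls2) | cls1 == "nocall" | cls2 == "nocall"
  parental <- mapply(function(a, j1, j2) {
    alleles <- c(parent1_geno$allele1[j1], parent1_geno$allele2[j1],
                 parent2_geno$allele1[j2], parent2_geno$allele2[j2])
    a %in% alleles[!is.na(alleles)]
  }, calls$allele, i1, i2)
  n_dropped_nocall <- sum(keep & nocall)
  out <- calls[keep & !nocall & parental, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nocall") <- n_dropped_nocall
  out
}

#' Run the full SNP filtering cascade for the two bulks
#'
#' Applies, in order: variant calling per cohort, removal of SNPs shared by
#' both bulks, the site-quality filter, and the multi-allelic /
#' non-parental exclusion. Returns the surviving bulk-specific calls
#' together with a per-stage ledger of counts in and out.
#'
#' @param hab_pileup,lab_pileup bulk pileups.
#' @param parent1_pileup,parent2_pileup parent pileups (donor, recurrent).
#' @param ref reference table or [genome_model()].
#' @param bulk_params,parent_params [call_params()] for bulks and parents.
#' @param min_phred site-quality threshold (default 30).
#' @param min_allele_reads multi-allelic noise floor (default 2).
#' @return list(`hab`, `lab` (filtered call tables), `parent1_geno`,
#'   `parent2_geno`, `log` (data.frame stage/cohort/n)).
#' @export
filter_cascade <- function(hab_pileup, lab_pileup, parent1_pileup,
                           parent2_pileup, ref,
                           bulk_params = bulk_call_params(),
                           parent_params = parent_call_params(),
                           min_phred = 30, min_allele_reads = 2) {
  hab0 <- call_variants(hab_pileup, ref, bulk_params)
  lab0 <- call_variants(lab_pileup, ref, bulk_params)
  p1 <- genotype_parents(parent1_pileup, ref, parent_params, min_allele_reads)
  p2 <- genotype_parents(parent2_pileup, ref, parent_params, min_allele_reads)
  sh <- filter_shared(hab0, lab0)
  hab1 <- filter_quality(sh$hab_only, min_phred)
  lab1 <- filter_quality(sh$lab_only, min_phred)
  pile <- list(hab_pileup, lab_pileup, parent1_pileup, parent2_pileup)
  hab2 <- filter_biallelic_parental(hab1, p1, p2, pile, min_allele_reads)
  lab2 <- filter_biallelic_parental(lab1, p1, p2, pile, min_allele_reads)
  log <- data.frame(
    stage = rep(c("called", "bulk_specific", "phred", "biallelic_parental"),
                each = 2),
    cohort = rep(c("HAB", "LAB"), 4),
    n = c(nrow(hab0), nrow(lab0), nrow(sh$hab_only), nrow(sh$lab_only),
          nrow(hab1), nrow(lab1), nrow(hab2), nrow(lab2))
  )
  list(hab = hab2, lab = lab2, parent1_geno = p1, parent2_geno = p2,
       log = log)
}
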