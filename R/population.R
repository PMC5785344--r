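# Forward-in-time simulation of a backcross-derived inbred population.
#
# An individual is a diploid mosaic of founder segments: per chromosome, two
# haplotypes, each stored compactly as a vector of segment end positions
# (`bp`, the last equal to the chromosome length) and a parallel vector of
# parental `origin` labels ("donor"/"recurrent"). Segments tile
# [1, length_bp] without gaps or overlaps.

.origins <- c("donor", "recurrent")

.new_hap <- function(bp, origin) list(bp = as.numeric(bp), origin = origin)

#' Founder individual (fully homozygous for one parental genome)
#'
#' @param genome a [genome_model()].
#' @param origin "donor" or "recurrent".
#' @param id sample identifier.
#' @return An individual: list with `id`, `haps` (per chromosome a list of
#'   two haplotypes) and `ac` (amylose content, `NA` until assigned).
#' @export
founder_individual <- function(genome, origin = c("donor", "recurrent"),
                               id = origin) {
  origin <- match.arg(origin)
  haps <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    h <- .new_hap(genome$chromosomes$length_bp[i], origin)
    list(h, h)
  })
  names(haps) <- genome$chromosomes$name
  list(id = id, haps = haps, ac = NA_real_)
}

# Parental origin of one haplotype at integer positions `pos`.
.hap_origin_at <- function(hap, pos) {
  idx <- findInterval(pos - 1e-9, hap$bp) + 1L
  idx[idx > length(hap$origin)] <- length(hap$origin)
  hap$origin[idx]
}

# Recombine two haplotypes of one chromosome given crossover points `xo`
# (strictly inside (1, len)) and a starting phase (1 or 2).
.recombine <- function(h1, h2, xo, phase_start, len) {
  if (length(xo) == 0) return(if (phase_start == 1) h1 else h2)
  ends <- sort(unique(c(h1$bp, h2$bp, xo)))
  if (ends[length(ends)] < len) ends <- c(ends, len)
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  # phase switches at each crossover
  phase <- (phase_start - 1L + findInterval(mids, xo)) %% 2L + 1L
  i1 <- pmin(findInterval(mids, h1$bp) + 1L, length(h1$origin))
  i2 <- pmin(findInterval(mids, h2$bp) + 1L, length(h2$origin))
  origin <- ifelse(phase == 1L, h1$origin[i1], h2$origin[i2])
  n <- length(origin)
  keep <- c(origin[-1] != origin[-n], TRUE)
  .new_hap(ends[keep], origin[keep])
}

#' Simulate one gamete (meiosis without interference)
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' genetic length in Morgans (Haldane model, no interference); crossover
#' positions are uniform in physical coordinates; the starting phase is
#' chosen at random. The returned haplotype tiles each chromosome exactly.
#'
#' @param parent an individual (see [founder_individual()]).
#' @param genome a [genome_model()].
#' @param seed optional integer seed (sets the global RNG).
#' @return A list of one recombinant haplotype per chromosome.
#' @export
simulate_gamete <- function(parent, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- genome$chromosomes
  if (any(chroms$length_bp <= 0)) stop("zero-length chromosome")
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length_bp[i]
    morgans <- chroms$length_cM[i] / 100
    hpair <- parent$haps[[chroms$name[i]]]
    n_xo <- stats::rpois(1L, morgans)
    xo <- if (n_xo > 0) sort(stats::runif(n_xo, min = 1, max = len)) else numeric(0)
    phase <- sample.int(2L, 1L)
    .recombine(hpair[[1]], hpair[[2]], xo, phase, len)
  })
  names(out) <- chroms$name
  out
}

.mate <- function(gam1, gam2, id) {
  haps <- lapply(names(gam1), function(cn) list(gam1[[cn]], gam2[[cn]]))
  names(haps) <- names(gam1)
  list(id = id, haps = haps, ac = NA_real_)
}

#' Breed a backcross-derived recombinant inbred population
#'
#' Pedigree: F1 (donor x recurrent), `n_backcross` backcrosses to the
#' recurrent parent, then `n_selfing` generations of selfing by single-seed
#' descent. The default (2 backcrosses, 7 selfings) yields a BC2F8
#' population under F1-to-F8 generation indexing: BC2F1 selfed seven times.
#' Each progeny descends through an independent pedigree.
#'
#' Expected donor-allele fraction per locus is (1/2)^(1 + n_backcross)
#' (12.5% for BC2) and expected residual heterozygosity is
#' (1/2)^(1 + n_backcross) * (1/2)^n_selfing (about 0.00195 for BC2F8).
#'
#' @param genome a [genome_model()].
#' @param n_progeny number of lines to produce (>= 1).
#' @param n_backcross backcrosses to the recurrent parent after the F1.
#' @param n_selfing selfing generations after the last backcross.
#' @param seed optional integer seed.
#' @param id_prefix prefix for line identifiers.
#' @return A list of individuals.
#' @export
breed_bc2f8 <- function(genome, n_progeny, n_backcross = 2, n_selfing = 7,
                        seed = NULL, id_prefix = "RIL") {
  stopifnot(n_progeny >= 1, n_backcross >= 0, n_selfing >= 0)
  if (!is.null(seed)) set.seed(seed)
  donor <- founder_individual(genome, "donor")
  recur <- founder_individual(genome, "recurrent")
  rec_gamete <- lapply(recur$haps, function(h) h[[1]])  # homozygous parent
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_progeny))
  lapply(ids, function(id) {
    ind <- .mate(lapply(donor$haps, function(h) h[[1]]), rec_gamete, id)  # F1
    for (b in seq_len(n_backcross)) {
      ind <- .mate(simulate_gamete(ind, genome), rec_gamete, id)
    }
    for (s in seq_len(n_selfing)) {
      ind <- .mate(simulate_gamete(ind, genome), simulate_gamete(ind, genome), id)
    }
    ind
  })
}

#' Donor-allele dosage matrix at founder sites
#'
#' @param population list of individuals.
#' @param genome a [genome_model()].
#' @return Integer matrix (individuals x sites) of donor-allele dosages
#'   0/1/2; rownames are sample ids, colnames `chrom:pos`.
#' @export
genotype_dosage <- function(population, genome) {
  sites <- genome$sites
  key <- paste0(sites$chrom, ":", sites$pos)
  out <- matrix(0L, nrow = length(population), ncol = nrow(sites),
                dimnames = list(vapply(population, `[[`, "", "id"), key))
  for (cn in unique(sites$chrom)) {
    sel <- which(sites$chrom == cn)
    pos <- sites$pos[sel]
    for (i in seq_along(population)) {
      hpair <- population[[i]]$haps[[cn]]
      d <- (.hap_origin_at(hpair[[1]], pos) == "donor") +
           (.hap_origin_at(hpair[[2]], pos) == "donor")
      out[i, sel] <- as.integer(d)
    }
  }
  out
}

#' Check that every haplotype tiles its chromosome exactly
#' @param individual an individual.
#' @param genome a [genome_model()].
#' @return TRUE invisibly, or an error describing the violation.
#' @export
check_tiling <- function(individual, genome) {
  for (i in seq_len(nrow(genome$chromosomes))) {
    cn <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length_bp[i]
    for (h in individual$haps[[cn]]) {
      if (length(h$bp) != length(h$origin)) stop("ragged haplotype on ", cn)
      if (any(diff(h$bp) <= 0)) stop("non-increasing segment ends on ", cn)
      if (abs(h$bp[length(h$bp)] - len) > 1e-6) stop("haplotype does not reach chromosome end on ", cn)
      if (!all(h$origin %in% .origins)) stop("unknown origin label on ", cn)
    }
  }
  invisible(TRUE)
}

#' Additive QTL model for the quantitative phenotype
#'
#' The phenotype (amylose content, % of total starch) is modelled as
#' baseline + sum over QTLs of effect x (donor dosage / 2) + Normal(0,
#' env_sd) noise: a line homozygous donor at a QTL gains the full effect,
#' a heterozygote half of it.
#'
#' @param baseline recurrent-parent mean phenotype (%).
#' @param qtls data.frame with columns `chrom`, `pos`, `effect`
#'   (additive effect per homozygous donor genotype, percentage points).
#' @param env_sd environmental (residual) standard deviation, >= 0.
#' @return An object of class `qtl_model`.
#' @export
qtl_model <- function(baseline, qtls, env_sd) {
  stopifnot(is.numeric(baseline), env_sd >= 0)
  stopifnot(all(c("chrom", "pos", "effect") %in% names(qtls)))
  structure(list(baseline = baseline, qtls = qtls, env_sd = env_sd),
            class = "qtl_model")
}

#' Default amylose QTL model
#'
#' One major QTL of +2.5 percentage points at the *GBSS1* position
#' (chr6:1,769,686) on a baseline of 23.2% (the recurrent-parent mean; the
#' donor parent is 25.7%), plus two minor QTLs of opposite sign (-1.2 at
#' chr1:30,038,502; +1.0 at chr11:18,288,616) sized so the simulated
#' population spans roughly 19-27% and segregates transgressively on both
#' sides of the parents. Environmental SD defaults to 0.8.
#'
#' @param env_sd environmental standard deviation (%).
#' @return A [qtl_model()].
#' @export
default_qtl_model <- function(env_sd = 0.8) {
  qtl_model(
    baseline = 23.2,
    qtls = data.frame(
      chrom = c("chr6", "chr1", "chr11"),
      pos = c(1769686L, 30038502L, 18288616L),
      effect = c(2.5, -1.2, 1.0)
    ),
    env_sd = env_sd
  )
}

#' Assign phenotypes to a simulated population
#'
#' @param population list of individuals.
#' @param genome a [genome_model()].
#' @param qtl a [qtl_model()]; every QTL position must be a founder site.
#' @param seed optional integer seed.
#' @return The population with the `ac` field filled in.
#' @export
assign_phenotypes <- function(population, genome, qtl = default_qtl_model(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(qtl$qtls) == 0) {
    genetic <- rep(qtl$baseline, length(population))
  } else {
    key <- paste0(genome$sites$chrom, ":", genome$sites$pos)
    qkey <- paste0(qtl$qtls$chrom, ":", qtl$qtls$pos)
    if (!all(qkey %in% key)) {
      stop("QTL position(s) not in the founder site map: ",
           paste(setdiff(qkey, key), collapse = ", "))
    }
    dos <- genotype_dosage(population, genome)[, qkey, drop = FALSE]
    genetic <- qtl$baseline + as.numeric(dos %*% (qtl$qtls$effect / 2))
  }
  noise <- if (qtl$env_sd > 0) stats::rnorm(length(population), 0, qtl$env_sd) else 0
  ac <- genetic + noise
  for (i in seq_along(population)) population[[i]]$ac <- ac[i]
  population
}

#' Phenotype table of a population
#' @param population list of individuals with phenotypes assigned.
#' @return data.frame with columns `id`, `ac`.
#' @export
phenotype_table <- function(population) {
  data.frame(
    id = vapply(population, `[[`, "", "id"),
    ac = vapply(population, `[[`, 0, "ac")
  )
}
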