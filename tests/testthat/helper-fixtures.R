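# Small programmatic fixtures shared across the test files.

# Compact genome: `n_chrom` chromosomes of `len_bp` with `n_sites` evenly
# spaced founder sites each and a uniform genetic length.
toy_genome <- function(n_chrom = 2, len_bp = 2e6, len_cM = 100, n_sites = 20) {
  chroms <- data.frame(name = paste0("c", seq_len(n_chrom)),
                       length_bp = len_bp, length_cM = len_cM)
  sites <- do.call(rbind, lapply(chroms$name, function(cn) {
    data.frame(chrom = cn,
               pos = round(seq(len_bp / n_sites, len_bp, length.out = n_sites)),
               donor = "A", recurrent = "G")
  }))
  genome_model(chroms, sites)
}

# One-row wide pileup with explicit allele counts.
make_pileup <- function(chrom, pos, A = 0, C = 0, G = 0, T = 0,
                        sample = "X", phred = 40) {
  data.frame(chrom = chrom, pos = pos, sample = sample,
             A = A, C = C, G = G, T = T,
             depth = A + C + G + T, phred = phred)
}

# Parent genotype rows for classify_candidates tests.
make_parent_geno <- function(chrom, pos, class, allele1, allele2 = NA_character_) {
  data.frame(chrom = chrom, pos = pos, class = class,
             allele1 = allele1, allele2 = allele2)
}
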