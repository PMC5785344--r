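# Plain-text interchange: TSV tables and a minimal VCF v4.2 representation
# of per-site, per-cohort read counts (FORMAT fields DP and AD).

#' Read/write tab-separated tables
#'
#' Thin wrappers with the package's conventions (no quoting, no row names,
#' header line, tab separator).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data.frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write cohort pileups as minimal VCF v4.2
#'
#' One record per site; REF is the reference allele, ALT the comma-joined
#' non-reference alleles observed in any cohort (or `.` when none), QUAL
#' the site phred score (maximum across cohorts), and one genotype column
#' per cohort with FORMAT `DP:AD` where AD lists the depths of REF and
#' each ALT allele in order.
#'
#' @param pileups named list of cohort pileup data.frames covering the
#'   same sites (names become VCF sample columns).
#' @param ref data.frame `chrom`, `pos`, `ref` or a [genome_model()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_pileup_vcf <- function(pileups, ref, path) {
  stopifnot(length(pileups) >= 1, !is.null(names(pileups)))
  if (inherits(ref, "genome_model")) {
    ref <- data.frame(chrom = ref$sites$chrom, pos = ref$sites$pos,
                      ref = ref$sites$recurrent)
  }
  base <- pileups[[1]][, c("chrom", "pos")]
  key <- paste0(base$chrom, ":", base$pos)
  for (p in pileups) {
    if (!identical(paste0(p$chrom, ":", p$pos), key)) {
      stop("all cohort pileups must cover the same sites in the same order")
    }
  }
  ridx <- match(key, paste0(ref$chrom, ":", ref$pos))
  if (anyNA(ridx)) stop("site(s) missing from the reference table")
  refallele <- ref$ref[ridx]
  nuc <- c("A", "C", "G", "T")
  count_mats <- lapply(pileups, function(p) as.matrix(p[, nuc]))
  total <- Reduce(`+`, count_mats)
  qual <- do.call(pmax, lapply(pileups, `[[`, "phred"))

  records <- vapply(seq_along(key), function(i) {
    alts <- nuc[nuc != refallele[i] & total[i, ] > 0]
    alleles <- c(refallele[i], alts)
    alt_field <- if (length(alts) == 0) "." else paste(alts, collapse = ",")
    geno <- vapply(count_mats, function(cm) {
      paste0(sum(cm[i, ]), ":", paste(cm[i, alleles], collapse = ","))
    }, "")
    paste(c(base$chrom[i], base$pos[i], ".", refallele[i], alt_field,
            format(qual[i]), "PASS", ".", "DP:AD", geno), collapse = "\t")
  }, "")

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref first)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(pileups)), collapse = "\t")
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read cohort pileups from a minimal VCF
#'
#' Parses a VCF written by [write_pileup_vcf()] (or any VCF with per-sample
#' DP/AD fields) via [vcfR::read.vcfR()] and reconstructs the wide per-site
#' count table for each sample column.
#'
#' @param path VCF file path.
#' @return named list of pileup data.frames (`chrom`, `pos`, `sample`,
#'   `A`, `C`, `G`, `T`, `depth`, `phred`).
#' @export
read_pileup_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  nuc <- c("A", "C", "G", "T")
  samples <- colnames(ad)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  lapply(stats::setNames(samples, samples), function(s) {
    counts <- matrix(0L, nrow = nrow(ad), ncol = 4,
                     dimnames = list(NULL, nuc))
    for (i in seq_len(nrow(ad))) {
      alt <- fix[i, "ALT"]
      alleles <- c(fix[i, "REF"],
                   if (!is.na(alt) && alt != ".") strsplit(alt, ",")[[1]])
      depths <- as.integer(strsplit(ad[i, s], ",")[[1]])
      counts[i, alleles] <- depths
    }
    out <- data.frame(chrom = chrom, pos = pos, sample = s,
                      counts[, 1], counts[, 2], counts[, 3], counts[, 4],
                      depth = rowSums(counts), phred = qual)
    names(out)[4:7] <- nuc
    out
  })
}
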