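# Codon-coordinate arithmetic and amino-acid-effect prediction for CDS
# substitutions (standard nuclear genetic code; positions count spliced CDS
# bases from the A of the start ATG = 1).

.aa3 <- function(aa1) {
  code <- Biostrings::AMINO_ACID_CODE
  out <- unname(code[aa1])
  out[aa1 == "*"] <- "Ter"
  out
}

.aa1 <- function(aa3) {
  code <- Biostrings::AMINO_ACID_CODE
  i <- match(aa3, code)
  out <- names(code)[i]
  out[aa3 %in% c("Ter", "Stop", "*")] <- "*"
  if (anyNA(out)) stop("unknown amino acid code: ",
                       paste(aa3[is.na(out)], collapse = ", "))
  out
}

#' Codon index and offset of a CDS position
#'
#' Positions are numbered from the translation start codon (the A of the
#' ATG is position 1). Codon index is 1-based (equal to the protein residue
#' number); the offset is 0, 1 or 2 within the codon. Vectorised.
#'
#' @param cds_position 1-based CDS position(s), >= 1.
#' @return data.frame with columns `codon_index` and `codon_offset`.
#' @examples
#' codon_of(1582)  # codon 528, offset 0: residue 528 of the protein
#' @export
codon_of <- function(cds_position) {
  if (any(cds_position < 1)) stop("CDS positions are 1-based (>= 1)")
  data.frame(codon_index = as.integer((cds_position - 1) %/% 3 + 1),
             codon_offset = as.integer((cds_position - 1) %% 3))
}

#' Predict the amino-acid effect of a CDS substitution
#'
#' Given the reference amino acid at the affected codon, the candidate
#' reference codons are those coding for `ref_aa` whose base at the codon
#' offset equals `ref_base`; the substitution is applied to each and the
#' resulting amino acids translated under the standard genetic code. If a
#' single amino acid results, the prediction is unambiguous.
#'
#' @param cds_position 1-based CDS position of the substitution.
#' @param ref_base,alt_base reference and substituted nucleotides
#'   (distinct).
#' @param ref_aa reference amino acid, 3-letter code (e.g. `"Asp"`).
#' @return list: `codon_index`, `codon_offset`, `ref_codons`,
#'   `alt_codons`, `alt_aa` (3-letter codes, unique), `synonymous`
#'   (all alternatives equal `ref_aa`), `unambiguous`.
#' @examples
#' predict_aa_change(1582, "G", "A", "Asp")$alt_aa  # "Asn"
#' @export
predict_aa_change <- function(cds_position, ref_base, alt_base, ref_aa) {
  stopifnot(length(cds_position) == 1, ref_base %in% c("A", "C", "G", "T"),
            alt_base %in% c("A", "C", "G", "T"))
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  co <- codon_of(cds_position)
  off <- co$codon_offset
  gc <- Biostrings::GENETIC_CODE
  aa1 <- .aa1(ref_aa)
  ref_codons <- names(gc)[gc == aa1 &
                          substr(names(gc), off + 1, off + 1) == ref_base]
  if (length(ref_codons) == 0) {
    stop(sprintf(
      "no codon of %s has base %s at offset %d (CDS position %d)",
      ref_aa, ref_base, off, cds_position))
  }
  alt_codons <- ref_codons
  substr(alt_codons, off + 1, off + 1) <- alt_base
  alt_aa <- unique(.aa3(unname(gc[alt_codons])))
  list(codon_index = co$codon_index, codon_offset = off,
       ref_codons = ref_codons, alt_codons = alt_codons, alt_aa = alt_aa,
       synonymous = all(alt_aa == ref_aa), unambiguous = length(alt_aa) == 1)
}

# ClustalW strong-similarity groups, used as the fixed class table for the
# descriptive "conservative substitution" label (Asp/Asn share NDEQ).
.conservative_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                          "MILV", "MILF", "HY", "FYW")

#' Is an amino-acid change conservative?
#'
#' Descriptive label only: two distinct residues are called conservative
#' when they share one of the fixed strong-similarity groups; no scoring
#' claim is made.
#'
#' @param ref_aa,alt_aa 3-letter amino acid codes.
#' @return logical.
#' @export
is_conservative <- function(ref_aa, alt_aa) {
  a <- .aa1(ref_aa)
  b <- .aa1(alt_aa)
  mapply(function(x, y) {
    if (x == y) return(TRUE)
    any(vapply(.conservative_groups, function(g) {
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE)
    }, logical(1)))
  }, a, b, USE.NAMES = FALSE)
}

#' Annotate a table of CDS substitutions
#'
#' Applies [codon_of()] and [predict_aa_change()] row-wise to a
#' substitution table (mirroring a position / SNP / amino-acid-change
#' report) and adds the derived codon coordinates, predicted amino
#' acid(s), synonymy and the conservative-change label.
#'
#' @param substitutions data.frame with columns `cds_position`, `ref_base`,
#'   `alt_base`, `ref_aa` (3-letter).
#' @return The input with added columns `codon_index`, `codon_offset`,
#'   `alt_aa` (multiple possibilities joined by "/"), `change`
#'   (e.g. `"Asp to Asn"`), `synonymous`, `unambiguous`, `conservative`
#'   (`NA` when the prediction is ambiguous or synonymous).
#' @export
annotate_cds <- function(substitutions) {
  need <- c("cds_position", "ref_base", "alt_base", "ref_aa")
  stopifnot(all(need %in% names(substitutions)))
  res <- lapply(seq_len(nrow(substitutions)), function(i) {
    s <- substitutions[i, ]
    predict_aa_change(s$cds_position, s$ref_base, s$alt_base, s$ref_aa)
  })
  substitutions$codon_index <- vapply(res, `[[`, 0L, "codon_index")
  substitutions$codon_offset <- vapply(res, `[[`, 0L, "codon_offset")
  substitutions$alt_aa <- vapply(res, function(r) paste(r$alt_aa, collapse = "/"), "")
  substitutions$change <- paste(substitutions$ref_aa, "to", substitutions$alt_aa)
  substitutions$synonymous <- vapply(res, `[[`, TRUE, "synonymous")
  substitutions$unambiguous <- vapply(res, `[[`, TRUE, "unambiguous")
  substitutions$conservative <- ifelse(
    substitutions$synonymous | !substitutions$unambiguous, NA,
    mapply(function(r, a) if (length(r$alt_aa) == 1) is_conservative(a, r$alt_aa) else NA,
           res, substitutions$ref_aa))
  substitutions
}
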