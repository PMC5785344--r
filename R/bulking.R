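#' Constitute high/low phenotypic bulks from a phenotype table
#'
#' Selects the `n_per_bulk` individuals at each extreme of the phenotype
#' distribution: the low bulk (LAB) takes the smallest values, the high
#' bulk (HAB) the largest. Selection is deterministic under ties: the low
#' bulk is filled first by (phenotype ascending, id ascending), then the
#' high bulk from the remaining individuals by (phenotype descending, id
#' ascending), which keeps the bulks disjoint even when all phenotypes tie.
#' Output does not depend on the row order of the input.
#'
#' @param phenotypes data.frame with columns `id` and `ac` (phenotype,
#'   e.g. amylose as % of total starch); ids unique, values finite.
#' @param n_per_bulk bulk size (default 10 individuals per bulk).
#' @return A list with elements `HAB` and `LAB`, each a `bulk_definition`:
#'   list(`label`, `members` (ids), `ac_range` = c(min, max)).
#' @examples
#' ph <- data.frame(id = sprintf("L%03d", 1:100), ac = seq(1, 100))
#' b <- select_bulks(ph, 10)
#' b$HAB$ac_range
#' @export
select_bulks <- function(phenotypes, n_per_bulk = 10) {
  stopifnot(is.data.frame(phenotypes),
            all(c("id", "ac") %in% names(phenotypes)), n_per_bulk >= 1)
  if (anyDuplicated(phenotypes$id)) stop("duplicated sample ids")
  if (any(!is.finite(phenotypes$ac))) stop("non-finite phenotype values")
  if (nrow(phenotypes) < 2 * n_per_bulk) {
    stop("need at least ", 2 * n_per_bulk, " phenotyped individuals")
  }
  ph <- phenotypes[order(phenotypes$ac, phenotypes$id), , drop = FALSE]
  lab <- ph[seq_len(n_per_bulk), , drop = FALSE]
  rest <- ph[-seq_len(n_per_bulk), , drop = FALSE]
  rest <- rest[order(-rest$ac, rest$id), , drop = FALSE]
  hab <- rest[seq_len(n_per_bulk), , drop = FALSE]
  mk <- function(label, d) {
    structure(list(label = label, members = d$id,
                   ac_range = range(d$ac)), class = "bulk_definition")
  }
  list(HAB = mk("HAB", hab), LAB = mk("LAB", lab))
}

#' @exportS3Method base::print
print.bulk_definition <- function(x, ...) {
  cat(sprintf("%s: %d members, phenotype range [%.2f, %.2f]\n",
              x$label, length(x$members), x$ac_range[1], x$ac_range[2]))
  invisible(x)
}
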