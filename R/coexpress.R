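# Guide-gene co-expression screening by (optionally weighted) Pearson
# correlation on a genes x samples expression matrix.

#' Pearson correlation, optionally weighted
#'
#' Unweighted, this is the standard product-moment correlation
#' ([stats::cor()]). With per-sample weights, the weighted means and
#' covariances are used (weights normalised to sum to one, via
#' [stats::cov.wt()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param weights optional non-negative per-sample weights.
#' @return correlation coefficient in [-1, 1].
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 2, 4))  # 0.9820
#' @export
pearson_cor <- function(x, y, weights = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  if (is.null(weights)) return(stats::cor(x, y))
  stopifnot(length(weights) == length(x), all(weights >= 0), sum(weights) > 0)
  stats::cov.wt(cbind(x, y), wt = weights / sum(weights),
                cor = TRUE, method = "ML")$cor[1, 2]
}

#' Screen candidate genes against guide genes
#'
#' Computes every candidate x guide correlation on an expression matrix
#' and flags pairs whose coefficient reaches the cutoff (>=, so a
#' coefficient exactly at the cutoff passes). Rows are sorted by candidate,
#' then by descending coefficient.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns; >= 3 samples.
#' @param guide_genes,candidate_genes character vectors of gene ids present
#'   in `expr`.
#' @param cutoff minimum correlation to declare co-expression
#'   (default 0.6).
#' @param weights optional per-sample weights.
#' @return data.frame: `candidate`, `guide`, `r`, `passes_cutoff`.
#' @export
screen_guides <- function(expr, guide_genes, candidate_genes, cutoff = 0.6,
                          weights = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  unknown <- setdiff(c(guide_genes, candidate_genes), rownames(expr))
  if (length(unknown) > 0) {
    stop("gene id(s) not in expression matrix: ",
         paste(unknown, collapse = ", "))
  }
  grid <- expand.grid(candidate = candidate_genes, guide = guide_genes,
                      stringsAsFactors = FALSE)
  grid$r <- mapply(function(cand, gd) {
    pearson_cor(expr[cand, ], expr[gd, ], weights)
  }, grid$candidate, grid$guide)
  grid$passes_cutoff <- grid$r >= cutoff
  grid <- grid[order(grid$candidate, -grid$r), ]
  rownames(grid) <- NULL
  grid
}

#' Synthetic co-expression matrix with planted correlations
#'
#' Guide profiles are iid standard normal across samples; each candidate
#' gene is alpha * g + sqrt(1 - alpha^2) * noise against its assigned guide
#' (cycling through the guides), so its expected Pearson correlation with
#' that guide is alpha. Background genes are pure noise.
#'
#' @param n_samples number of samples (columns).
#' @param n_guides number of guide genes.
#' @param alphas planted correlations, one per candidate gene.
#' @param n_background additional uncorrelated genes.
#' @param seed optional integer seed.
#' @return list: `expr` (matrix), `truth` (data.frame `candidate`,
#'   `guide`, `alpha`), `guides`, `candidates`.
#' @export
simulate_coexpression <- function(n_samples = 40, n_guides = 3,
                                  alphas = rep(0.7, 6), n_background = 0,
                                  seed = NULL) {
  stopifnot(n_samples >= 3, n_guides >= 1, all(abs(alphas) <= 1))
  if (!is.null(seed)) set.seed(seed)
  guides <- sprintf("guide%02d", seq_len(n_guides))
  candidates <- sprintf("cand%02d", seq_along(alphas))
  g <- matrix(stats::rnorm(n_guides * n_samples), nrow = n_guides,
              dimnames = list(guides, NULL))
  assigned <- (seq_along(alphas) - 1L) %% n_guides + 1L
  cand <- t(vapply(seq_along(alphas), function(i) {
    alphas[i] * g[assigned[i], ] +
      sqrt(1 - alphas[i]^2) * stats::rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(cand) <- candidates
  expr <- rbind(g, cand)
  if (n_background > 0) {
    bg <- matrix(stats::rnorm(n_background * n_samples), nrow = n_background,
                 dimnames = list(sprintf("bg%03d", seq_len(n_background)), NULL))
    expr <- rbind(expr, bg)
  }
  colnames(expr) <- sprintf("S%02d", seq_len(n_samples))
  list(expr = expr,
       truth = data.frame(candidate = candidates, guide = guides[assigned],
                          alpha = alphas),
       guides = guides, candidates = candidates)
}
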