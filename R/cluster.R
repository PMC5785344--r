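# Single-linkage clustering of candidate markers into genomic regions
# (linkage-drag blocks around a selected locus).

#' Cluster candidate markers into candidate regions
#'
#' Single-linkage merge: consecutive candidates on the same chromosome
#' whose gap is at most `max_gap` join one region. Region start/end are the
#' min/max member positions (1-based inclusive), the physical span is
#' `end - start`, and the approximate genetic span is span in Mbp times the
#' configured map rate. The result does not depend on the input row order.
#'
#' @param candidates data.frame with columns `chrom` and `pos`.
#' @param max_gap maximum intra-region gap in bp (> 0; default 1 Mb).
#' @param cm_per_mbp physical-to-genetic conversion rate (default 4.76
#'   cM/Mbp, under which a 2.1 Mbp block is about 10 cM).
#' @return data.frame of regions (`chrom`, `start`, `end`, `span_bp`,
#'   `span_mbp`, `span_cm`, `n`), ordered by chromosome and start, with
#'   attribute `"members"`: a data.frame mapping every candidate
#'   (`chrom`, `pos`) to its `region_id` (row index of the region table).
#' @examples
#' cands <- data.frame(chrom = "chr6", pos = c(1653659, 1769686, 3794599))
#' cluster_candidates(cands, max_gap = 2.5e6)$span_bp  # 2140940 (~2.1 Mbp)
#' @export
cluster_candidates <- function(candidates, max_gap = 1e6, cm_per_mbp = 4.76) {
  stopifnot(max_gap > 0, all(c("chrom", "pos") %in% names(candidates)))
  if (nrow(candidates) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      span_bp = numeric(), span_mbp = numeric(),
                      span_cm = numeric(), n = integer())
    attr(out, "members") <- data.frame(chrom = character(), pos = integer(),
                                       region_id = integer())
    return(out)
  }
  cand <- unique(candidates[, c("chrom", "pos")])
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  region_id <- integer(nrow(cand))
  next_id <- 0L
  for (cn in unique(cand$chrom)) {
    i <- which(cand$chrom == cn)
    gaps <- diff(cand$pos[i])
    new_region <- c(TRUE, gaps > max_gap)
    region_id[i] <- next_id + cumsum(new_region)
    next_id <- max(region_id[i])
  }
  sp <- split(seq_len(nrow(cand)), region_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(chrom = cand$chrom[i[1]],
               start = min(cand$pos[i]), end = max(cand$pos[i]),
               n = length(i))
  }))
  out$span_bp <- out$end - out$start
  out$span_mbp <- out$span_bp / 1e6
  out$span_cm <- out$span_mbp * cm_per_mbp
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "span_bp", "span_mbp", "span_cm", "n")]
  rownames(out) <- NULL
  # re-map member region ids to the ordered region table
  reg_key <- paste0(out$chrom, ":", out$start)
  mem_reg <- vapply(split(seq_len(nrow(cand)), region_id), function(i) {
    match(paste0(cand$chrom[i[1]], ":", min(cand$pos[i])), reg_key)
  }, 0L)
  members <- data.frame(chrom = cand$chrom, pos = cand$pos,
                        region_id = mem_reg[match(region_id, as.integer(names(mem_reg)))])
  rownames(members) <- NULL
  attr(out, "members") <- members
  out
}

#' Write candidate regions as BED
#'
#' Regions are reported 1-based inclusive internally (matching printed
#' genomic positions); BED output converts to the 0-based half-open
#' convention.
#'
#' @param regions output of [cluster_candidates()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
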