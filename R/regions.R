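#' Agglomerate significant CpG sites into DMRs
#'
#' Consecutive significant sites on the same chromosome whose gap is at most
#' `g` base pairs are chained into one region (adjacency linkage, the
#' convention shared by the established region callers; default g = 1000 bp).
#' Region boundaries are the positions of the first and last member probes
#' (no padding). Regions with fewer than `min_probes` members are dropped
#' with a message. Regions are ranked by their representative p-value (the
#' minimum raw p-value over member sites, ties resolved stably by genomic
#' order).
#'
#' @param significant_sites data frame with columns `chrom`, `pos`, `p_raw`,
#'   `p_adj`, sorted by chromosome then position.
#' @param g agglomeration gap in base pairs (> 0); default 1000.
#' @param min_probes minimum member count per region; default 2 (a single
#'   significant CpG is a differentially methylated position, not a region);
#'   set to 1 to keep single-probe regions.
#' @return Data frame of class `dmr_table` with columns `chrom`, `start`,
#'   `end`, `n_probes`, `p_rep`, `p_rep_adj`, `rank`, sorted by chromosome
#'   then start.
#' @export
agglomerate <- function(significant_sites, g = 1000, min_probes = 2) {
  if (g <= 0) stop("g must be > 0")
  if (min_probes < 1) stop("min_probes must be >= 1")
  s <- significant_sites
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_probes = integer(0), p_rep = numeric(0),
                      p_rep_adj = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("dmr_table", "data.frame")
  if (nrow(s) == 0L) return(empty)
  ord_ok <- !is.unsorted(order(s$chrom, s$pos)) &&
    all(order(s$chrom, s$pos) == seq_len(nrow(s)))
  if (!ord_ok) stop("significant sites must be sorted by (chromosome, position)")
  grp <- integer(nrow(s))
  gid <- 0L
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    brk <- c(TRUE, diff(s$pos[idx]) > g)
    grp[idx] <- gid + cumsum(brk)
    gid <- grp[idx[length(idx)]]
  }
  sp <- split(seq_len(nrow(s)), grp)
  recs <- lapply(sp, function(ii) {
    rp <- representative_p(s$p_raw[ii], s$p_adj[ii])
    data.frame(chrom = s$chrom[ii[1]], start = min(s$pos[ii]), end = max(s$pos[ii]),
               n_probes = length(ii), p_rep = rp$p_rep, p_rep_adj = rp$p_rep_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  drop <- out$n_probes < min_probes
  if (any(drop)) message(sum(drop), " region(s) with fewer than ", min_probes,
                         " probes dropped")
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$rank <- rank(out$p_rep, ties.method = "first")
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Representative p-value of a region
#'
#' The minimum p-value across member CpG sites quantifies the statistical
#' uncertainty of a region and is used to order regions by strength of
#' significance.
#'
#' @param p_raw member raw p-values (non-empty).
#' @param p_adj member BH-adjusted p-values.
#' @return List with `p_rep` (min raw) and `p_rep_adj` (min adjusted).
#' @export
representative_p <- function(p_raw, p_adj) {
  if (length(p_raw) == 0L) stop("region has no member sites")
  list(p_rep = min(p_raw), p_rep_adj = min(p_adj))
}

#' Write DMRs as BED6
#'
#' Converts 1-based closed probe-boundary coordinates to 0-based half-open
#' BED intervals (`start - 1`). The score is `min(1000, round(-10 * log10
#' p_rep))`.
#'
#' @param dmrs a `dmr_table` from [agglomerate()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$p_rep, 1e-300))))
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1, end = dmrs$end,
                    name = paste0("DMR_", seq_len(nrow(dmrs))), score = score,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
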