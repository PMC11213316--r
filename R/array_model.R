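#' Construct an array layout from probe coordinates
#'
#' An array layout holds the genomic coordinates of CpG probes, grouped by
#' chromosome and sorted by position. It is the source of probe gaps, of the
#' per-chromosome adaptive bandwidths, and of candidate regions in the
#' simulator. Coordinates are 1-based, following the Illumina manifest
#' convention.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based genomic positions (>= 1).
#' @param region_id optional character vector mapping each probe to a
#'   candidate-region identifier (`NA` for probes outside any region).
#' @return A data frame of class `array_layout` with columns `probe_id`,
#'   `chrom`, `pos` (and `region_id` if supplied), sorted by chromosome then
#'   position. Ties in position are retained.
#' @export
array_layout <- function(probe_id, chrom, pos, region_id = NULL) {
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  n <- length(probe_id)
  if (length(chrom) != n || length(pos) != n)
    stop("probe_id, chrom and pos must have equal length")
  keep <- !(is.na(chrom) | is.na(pos) | is.na(probe_id))
  if (!all(keep)) {
    message(sum(!keep), " probe(s) with missing coordinates dropped")
    probe_id <- probe_id[keep]; chrom <- chrom[keep]; pos <- pos[keep]
    if (!is.null(region_id)) region_id <- region_id[keep]
  }
  if (length(probe_id) == 0L) stop("empty layout: no probes with complete coordinates")
  if (anyDuplicated(probe_id)) stop("duplicated probe_id in layout: ",
                                    paste(utils::head(unique(probe_id[duplicated(probe_id)]), 3), collapse = ", "))
  if (any(pos < 1)) stop("positions must be >= 1 (1-based coordinates)")
  df <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                   stringsAsFactors = FALSE)
  if (!is.null(region_id)) df$region_id <- as.character(region_id)
  ord <- order(df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("array_layout", "data.frame")
  df
}

#' @export
print.array_layout <- function(x, ...) {
  cat("Array layout:", nrow(x), "probes on", length(unique(x$chrom)), "chromosome(s)\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Load a probe annotation table
#'
#' Reads probe coordinates either from a manifest-style CSV with columns
#' `probe_id,chrom,pos` (1-based positions) or from a BED3+ file
#' (`chrom,start,end,probe_id`, tab-separated, 0-based half-open starts, which
#' are converted to 1-based positions as `start + 1`).
#'
#' @param path path to the annotation file.
#' @param dialect `"manifest_csv"` or `"bed3plus"`.
#' @return An [array_layout()].
#' @export
load_probe_annotation <- function(path, dialect = c("manifest_csv", "bed3plus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "manifest_csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("probe_id", "chrom", "pos")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("annotation is missing required column(s): ",
                           paste(miss, collapse = ", "))
    array_layout(tab$probe_id, tab$chrom, tab$pos)
  } else {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 4) stop("BED3+ annotation needs at least 4 columns (chrom,start,end,name)")
    array_layout(tab[[4]], tab[[1]], tab[[2]] + 1L)
  }
}

#' Gaps between adjacent probes on one chromosome
#'
#' @param layout an [array_layout()].
#' @param chromosome chromosome name.
#' @return Numeric vector of base-pair gaps `pos[k+1] - pos[k]` (length one
#'   less than the probe count; empty if the chromosome has fewer than two
#'   probes).
#' @export
chromosome_gaps <- function(layout, chromosome) {
  p <- layout$pos[layout$chrom == chromosome]
  if (length(p) < 2L) return(numeric(0))
  diff(p)
}

#' Median probe spacing on a chromosome
#'
#' The adaptive bandwidth rule sets the kernel bandwidth of each chromosome to
#' this value. With an even number of gaps the median is the mean of the two
#' central gaps.
#'
#' @inheritParams chromosome_gaps
#' @param fixed_h fallback bandwidth (bp) when the chromosome has fewer than
#'   two probes and no gap exists.
#' @return Median gap in base pairs.
#' @export
median_gap <- function(layout, chromosome, fixed_h = 500) {
  g <- chromosome_gaps(layout, chromosome)
  if (length(g) == 0L) {
    warning("chromosome ", chromosome, " has < 2 probes; falling back to fixed bandwidth ", fixed_h, " bp")
    return(fixed_h)
  }
  stats::median(g)
}

#' Build a bandwidth policy
#'
#' In `fixed` mode (the faDMR method) every chromosome receives the same
#' bandwidth, by default 500 bp. In `adaptive` mode (the aaDMR method) each
#' chromosome's bandwidth equals its median probe spacing; chromosomes with a
#' single probe fall back to `fixed_h` with a warning.
#'
#' @param layout an [array_layout()].
#' @param mode `"fixed"` or `"adaptive"`.
#' @param fixed_h fixed bandwidth in base pairs (> 0); default 500.
#' @return A list of class `bandwidth_policy` with elements `mode`, `fixed_h`
#'   and `h`, a named vector mapping each chromosome to its bandwidth.
#' @export
make_bandwidth_policy <- function(layout, mode = c("fixed", "adaptive"), fixed_h = 500) {
  mode <- match.arg(mode)
  if (!is.numeric(fixed_h) || fixed_h <= 0) stop("fixed_h must be > 0")
  chroms <- unique(layout$chrom)
  h <- if (mode == "fixed") {
    stats::setNames(rep.int(as.numeric(fixed_h), length(chroms)), chroms)
  } else {
    stats::setNames(vapply(chroms, function(ch) median_gap(layout, ch, fixed_h), numeric(1)), chroms)
  }
  if (any(h <= 0)) stop("all bandwidths must be > 0")
  structure(list(mode = mode, fixed_h = as.numeric(fixed_h), h = h),
            class = "bandwidth_policy")
}

#' @export
print.bandwidth_policy <- function(x, ...) {
  cat("Bandwidth policy (", x$mode, " mode)\n", sep = "")
  print(round(x$h, 1))
  invisible(x)
}

#' Layout-emulation parameters
#'
#' Configuration for [emulate_layout()]. Each chromosome is a sequence of
#' units: promoter-like clusters of `cluster_size_range[1]` to
#' `cluster_size_range[2]` probes (uniform), and scattered singleton probes.
#' Within a cluster, gaps come from the "island" log-normal component (small
#' gaps); between units, from the "open-sea" component (large gaps). The
#' cluster frequency is set so that the fraction of island gaps equals
#' `island_weight`, making the pooled gap distribution the stated
#' two-component mixture. Clusters with at least `min_region_probes` members
#' are annotated as candidate regions.
#'
#' Defaults emulate a 450K-scale array: ~451,000 probes over 22 autosomes with
#' a gap distribution whose mode is well below 200 bp, whose right tail is
#' heavy, and whose per-chromosome median spacing lands at a few hundred base
#' pairs — the scale on which the fixed 500 bp bandwidth of established
#' kernel-based callers was chosen — qualitatively matching the published
#' probe-spacing histograms of the 450K/EPIC arrays (truncated at 1000 bp).
#'
#' @param probes_per_chrom named integer vector: probe count per chromosome.
#' @param island_weight target fraction of island (within-cluster) gaps among
#'   all gaps, in (0, 1).
#' @param island_meanlog,island_sdlog log-normal parameters of island gaps (bp).
#' @param opensea_meanlog,opensea_sdlog log-normal parameters of open-sea gaps.
#' @param cluster_size_range integer range of probes per promoter-like
#'   cluster (uniform).
#' @param min_region_probes minimum cluster size annotated as a candidate region.
#' @param start_pos position of the first probe on each chromosome.
#' @return A list of class `layout_config`.
#' @export
layout_config <- function(probes_per_chrom = stats::setNames(rep.int(20500L, 22L), paste0("chr", 1:22)),
                          island_weight = 0.55,
                          island_meanlog = log(100), island_sdlog = 0.9,
                          opensea_meanlog = log(4000), opensea_sdlog = 1.1,
                          cluster_size_range = c(4L, 12L),
                          min_region_probes = 4L,
                          start_pos = 15000L) {
  if (is.null(names(probes_per_chrom)) || any(!nzchar(names(probes_per_chrom))))
    stop("probes_per_chrom must be a named vector (chromosome -> probe count)")
  if (any(probes_per_chrom <= 0)) stop("probe counts must be positive")
  if (island_weight <= 0 || island_weight >= 1) stop("island_weight must be in (0,1)")
  if (length(cluster_size_range) != 2L || cluster_size_range[1] < 2L ||
      cluster_size_range[2] < cluster_size_range[1])
    stop("cluster_size_range must be an increasing pair with minimum >= 2")
  if (min_region_probes < 2) stop("min_region_probes must be >= 2")
  structure(list(probes_per_chrom = probes_per_chrom,
                 island_weight = island_weight,
                 island_meanlog = island_meanlog, island_sdlog = island_sdlog,
                 opensea_meanlog = opensea_meanlog, opensea_sdlog = opensea_sdlog,
                 cluster_size_range = as.integer(cluster_size_range),
                 min_region_probes = as.integer(min_region_probes),
                 start_pos = as.integer(start_pos)),
            class = "layout_config")
}

#' Emulate a methylation-array probe layout
#'
#' Generates a reproducible synthetic probe layout with clustered, irregular
#' spacing (see [layout_config()]) together with promoter-like candidate
#' regions usable as true/null regions in the simulator.
#'
#' @param config a [layout_config()].
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return An [array_layout()] whose `region_id` column maps probes to
#'   candidate regions (`NA` outside regions). The region table is attached as
#'   attribute `"regions"` and retrievable with [candidate_regions()].
#' @export
emulate_layout <- function(config = layout_config(), seed = NULL) {
  if (!inherits(config, "layout_config")) stop("config must be a layout_config")
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(config$probes_per_chrom)
  # probability that a unit is a cluster (vs a singleton probe), chosen so the
  # expected fraction of island gaps equals island_weight
  sbar <- mean(config$cluster_size_range)
  w <- config$island_weight
  p_cluster <- min(1, w / ((sbar - 1) - w * (sbar - 2)))
  per <- lapply(chroms, function(ch) {
    n <- as.integer(config$probes_per_chrom[[ch]])
    if (n == 1L) {
      return(list(pos = config$start_pos, cluster = 1L, in_cluster = FALSE))
    }
    # draw units (clusters or singletons) until n probes are covered
    n_units <- ceiling(n / (p_cluster * sbar + (1 - p_cluster))) + 50L
    repeat {
      is_cl <- stats::runif(n_units) < p_cluster
      size <- ifelse(is_cl,
                     sample(seq.int(config$cluster_size_range[1],
                                    config$cluster_size_range[2]),
                            n_units, replace = TRUE), 1L)
      if (sum(size) >= n) break
      n_units <- n_units * 2L
    }
    last <- which(cumsum(size) >= n)[1]
    size <- size[seq_len(last)]
    size[last] <- size[last] - (sum(size) - n)   # truncate final unit
    unit <- rep(seq_along(size), size)
    island <- unit[-1] == unit[-n]               # gap within a unit
    gap <- numeric(n - 1L)
    gap[island] <- stats::rlnorm(sum(island), config$island_meanlog, config$island_sdlog)
    gap[!island] <- stats::rlnorm(sum(!island), config$opensea_meanlog, config$opensea_sdlog)
    gap <- pmax(1, round(gap))
    pos <- config$start_pos + cumsum(c(0, gap))
    list(pos = pos, cluster = unit, in_cluster = size[unit] > 1L)
  })
  n_tot <- sum(lengths(lapply(per, `[[`, "pos")))
  probe_id <- sprintf("cg%08d", seq_len(n_tot))
  chrom <- rep(chroms, vapply(per, function(z) length(z$pos), integer(1)))
  pos <- unlist(lapply(per, `[[`, "pos"), use.names = FALSE)

  # annotate clusters with enough probes as candidate regions
  region_id <- rep(NA_character_, n_tot)
  regions <- vector("list", length(chroms))
  off <- 0L
  for (k in seq_along(chroms)) {
    cl <- per[[k]]$cluster
    p <- per[[k]]$pos
    sz <- tabulate(cl)
    keep <- which(sz >= config$min_region_probes)
    if (length(keep)) {
      ids <- sprintf("reg_%s_%05d", chroms[k], seq_along(keep))
      idx <- match(cl, keep)              # candidate index or NA
      region_id[off + seq_along(cl)] <- ifelse(is.na(idx), NA_character_, ids[idx])
      start <- vapply(keep, function(c0) min(p[cl == c0]), numeric(1))
      end <- vapply(keep, function(c0) max(p[cl == c0]), numeric(1))
      regions[[k]] <- data.frame(region_id = ids, chrom = chroms[k],
                                 start = start, end = end, n_probes = sz[keep],
                                 feature_class = ifelse(end - start <= 200,
                                                        "TSS200-like", "TSS1500-like"),
                                 stringsAsFactors = FALSE)
    }
    off <- off + length(cl)
  }
  reg <- do.call(rbind, regions[!vapply(regions, is.null, logical(1))])
  rownames(reg) <- NULL
  out <- array_layout(probe_id, chrom, pos, region_id = region_id)
  attr(out, "regions") <- reg
  out
}

#' Candidate regions attached to an emulated layout
#'
#' @param layout an [array_layout()] produced by [emulate_layout()].
#' @return Data frame with columns `region_id,chrom,start,end,n_probes,feature_class`.
#' @export
candidate_regions <- function(layout) {
  reg <- attr(layout, "regions")
  if (is.null(reg)) stop("layout carries no candidate-region annotation")
  reg
}

#' Export a gap histogram as TSV
#'
#' Writes the per-chromosome pooled gap distribution as `gap_bp,count` pairs
#' (gaps above `truncate_at` pooled into one overflow bin), mirroring the
#' truncated histograms used for array QC.
#'
#' @param layout an [array_layout()].
#' @param path output TSV path.
#' @param binwidth histogram bin width in bp.
#' @param truncate_at upper truncation in bp.
#' @export
write_gap_histogram <- function(layout, path, binwidth = 50, truncate_at = 1000) {
  gaps <- unlist(lapply(unique(layout$chrom), function(ch) chromosome_gaps(layout, ch)),
                 use.names = FALSE)
  brk <- c(seq(0, truncate_at, by = binwidth), Inf)
  cnt <- table(cut(gaps, brk, right = TRUE, include.lowest = TRUE))
  out <- data.frame(gap_bp = c(seq(binwidth, truncate_at, by = binwidth),
                               paste0(">", truncate_at)),
                    count = as.integer(cnt))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
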