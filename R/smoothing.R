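#' Gaussian kernel
#'
#' `K(z) = exp(-z^2 / 2)`, the kernel used to weight neighboring CpG sites by
#' their scaled genomic distance `z = (x_j - x_i) / h`.
#'
#' @param z dimensionless distance(s).
#' @return Kernel weight(s) in (0, 1]; `K(0) = 1`, symmetric in `z`.
#' @export
gaussian_kernel <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  exp(-z^2 / 2)
}

#' Normalized kernel weights at one site
#'
#' Neighbors of site `i` are all other sites within `W` base pairs. Each
#' neighbor `j` receives weight
#' `w_j = K((x_j - x_i)/h) / sum_{j != i} K((x_j - x_i)/h)`,
#' so that the weights of a non-empty neighbor set sum to one: every site's
#' neighborhood contributes a fixed total of information regardless of local
#' probe density. The site itself is excluded from the sum. Sites at duplicate
#' coordinates participate with `K(0) = 1`.
#'
#' @param positions sorted base-pair positions of one chromosome.
#' @param i index of the center site.
#' @param h bandwidth in base pairs (> 0).
#' @param W truncation window in base pairs; default `5 * h` (the discarded
#'   kernel factor is at most `exp(-12.5)`).
#' @return List of class `neighbor_set`: `center_index`, `neighbor_indices`,
#'   `distances` (signed, bp), `weights`. Empty neighbor sets are valid.
#' @export
normalized_weights <- function(positions, i, h, W = 5 * h) {
  if (h <= 0) stop("bandwidth h must be > 0")
  if (is.unsorted(positions)) stop("positions must be sorted")
  idx <- .window_indices(positions, W)
  j <- setdiff(seq.int(idx$lo[i], idx$hi[i]), i)
  d <- positions[j] - positions[i]
  keep <- abs(d) <= W
  j <- j[keep]; d <- d[keep]
  k <- gaussian_kernel(d / h)
  structure(list(center_index = i, neighbor_indices = j, distances = d,
                 weights = if (length(k)) k / sum(k) else numeric(0)),
            class = "neighbor_set")
}

# first/last candidate neighbor index within +/- W of every site
.window_indices <- function(positions, W) {
  n <- length(positions)
  lo <- findInterval(positions - W, positions) + 1L  # first index with pos > p - W
  # include boundary/duplicate positions exactly at distance W
  for (i in seq_len(n)) {
    while (lo[i] > 1L && positions[lo[i] - 1L] >= positions[i] - W) lo[i] <- lo[i] - 1L
  }
  hi <- findInterval(positions + W, positions)       # last index with pos <= p + W
  list(lo = lo, hi = hi)
}

#' Smooth squared site statistics along a chromosome
#'
#' Computes the locally weighted statistic
#' `S(x_i) = y_i + sum_{j != i} w_j(x_i) * y_j`
#' with normalized Gaussian-kernel weights, for every site of one chromosome,
#' using a sliding window over the sorted positions (O(n * k), k = mean
#' neighbors). Also returns the weight sums needed by the Satterthwaite
#' approximation: `sum_w = sum w_j` (1 for any site with neighbors, 0 for an
#' isolated site, for which `S = y_i`) and `sum_w2 = sum w_j^2`.
#'
#' @param y per-site squared moderated t-statistics (aligned with `positions`).
#' @param positions sorted base-pair positions.
#' @param h bandwidth in base pairs.
#' @param W truncation window; default `5 * h`.
#' @return Data frame with columns `S`, `sum_w`, `sum_w2`, `n_neighbors`.
#' @export
smooth_chromosome <- function(y, positions, h, W = 5 * h) {
  if (length(y) != length(positions))
    stop("y and positions must have the same length")
  if (h <= 0) stop("bandwidth h must be > 0")
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(y)
  S <- numeric(n); sum_w <- numeric(n); sum_w2 <- numeric(n); nn <- integer(n)
  idx <- .window_indices(positions, W)
  inv2h2 <- 1 / (2 * h^2)
  for (i in seq_len(n)) {
    lo <- idx$lo[i]; hi <- idx$hi[i]
    if (hi - lo < 1L) { S[i] <- y[i]; next }  # no neighbor besides self
    j <- lo:hi
    j <- j[j != i]
    d <- positions[j] - positions[i]
    k <- exp(-d * d * inv2h2)
    sk <- sum(k)
    w <- k / sk
    S[i] <- y[i] + sum(w * y[j])
    sum_w[i] <- 1
    sum_w2[i] <- sum(w * w)
    nn[i] <- length(j)
  }
  data.frame(S = S, sum_w = sum_w, sum_w2 = sum_w2, n_neighbors = nn)
}

#' Bandwidth for a chromosome under a policy
#'
#' @param policy a [make_bandwidth_policy()] result.
#' @param chromosome chromosome name.
#' @return Bandwidth in base pairs.
#' @export
choose_h <- function(policy, chromosome) {
  stopifnot(inherits(policy, "bandwidth_policy"))
  if (!chromosome %in% names(policy$h))
    stop("chromosome not covered by bandwidth policy: ", chromosome)
  unname(policy$h[[chromosome]])
}

#' Smooth site statistics genome-wide
#'
#' Applies [smooth_chromosome()] per chromosome with the bandwidth given by
#' the policy. Smoothing never crosses chromosome boundaries.
#'
#' @param sites data frame with columns `probe_id`, `chrom`, `pos`, `y`
#'   (sorted by chromosome then position).
#' @param policy a [make_bandwidth_policy()] result.
#' @param window_mult truncation window as a multiple of h; default 5.
#' @return `sites` with columns `S`, `sum_w`, `sum_w2`, `n_neighbors`, `h`
#'   appended.
#' @export
smooth_sites <- function(sites, policy, window_mult = 5) {
  need <- c("chrom", "pos", "y")
  if (!all(need %in% names(sites))) stop("sites must have columns chrom, pos, y")
  out <- vector("list", length(unique(sites$chrom)))
  chroms <- unique(sites$chrom)
  for (k in seq_along(chroms)) {
    sub <- sites[sites$chrom == chroms[k], , drop = FALSE]
    h <- choose_h(policy, chroms[k])
    sm <- smooth_chromosome(sub$y, sub$pos, h, W = window_mult * h)
    sub$S <- sm$S; sub$sum_w <- sm$sum_w; sub$sum_w2 <- sm$sum_w2
    sub$n_neighbors <- sm$n_neighbors; sub$h <- h
    out[[k]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
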