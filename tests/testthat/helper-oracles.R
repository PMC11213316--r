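# Independent brute-force oracles and tiny fixture builders used across tests.

# all-pairs O(n^2) evaluation of the normalized kernel-weighted statistic
bf_smooth <- function(y, positions, h, W = 5 * h) {
  n <- length(y)
  S <- numeric(n); sum_w <- numeric(n); sum_w2 <- numeric(n); nn <- integer(n)
  for (i in seq_len(n)) {
    d <- positions - positions[i]
    j <- which(abs(d) <= W & seq_len(n) != i)
    if (length(j) == 0L) { S[i] <- y[i]; next }
    k <- exp(-((positions[j] - positions[i]) / h)^2 / 2)
    w <- k / sum(k)
    S[i] <- y[i] + sum(w * y[j])
    sum_w[i] <- sum(w); sum_w2[i] <- sum(w^2); nn[i] <- length(j)
  }
  data.frame(S = S, sum_w = sum_w, sum_w2 = sum_w2, n_neighbors = nn)
}

# naive transitive-closure grouping of significant sites within gap g,
# per chromosome (O(n^2))
bf_agglomerate <- function(sites, g) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    linked <- abs(outer(s$pos, s$pos, "-")) <= g
    grp <- seq_len(n)
    repeat {   # propagate links to a fixed point
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (linked[i, j] && grp[j] != grp[i]) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (gg in unique(grp)) {
      ii <- which(grp == gg)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(s$pos[ii]), end = max(s$pos[ii]),
        n_probes = length(ii), p_rep = min(s$p_raw[ii]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# O(n*m) interval-overlap classification oracle
bf_classify <- function(called, truth_true, criterion) {
  n_calls <- nrow(called); n_true <- nrow(truth_true)
  call_tp <- logical(n_calls); true_hit <- logical(n_true)
  for (i in seq_len(n_calls)) for (j in seq_len(n_true)) {
    same_ch <- called$chrom[i] == truth_true$chrom[j]
    hit <- if (criterion == "EO") {
      same_ch && called$start[i] == truth_true$start[j] &&
        called$end[i] == truth_true$end[j]
    } else {
      same_ch && called$start[i] <= truth_true$end[j] &&
        called$end[i] >= truth_true$start[j]
    }
    if (hit) { call_tp[i] <- TRUE; true_hit[j] <- TRUE }
  }
  list(TP = sum(true_hit), FP = sum(!call_tp))
}

# manual BH step-up (independent of stats::p.adjust)
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# layout with explicit coordinates, bypassing the emulator
tiny_layout <- function(pos_by_chrom, region_id = NULL) {
  chrom <- rep(names(pos_by_chrom), lengths(pos_by_chrom))
  pos <- unlist(pos_by_chrom, use.names = FALSE)
  array_layout(sprintf("cg%05d", seq_along(pos)), chrom, pos, region_id = region_id)
}

# small emulated layout shared by several stochastic tests
small_emulated_layout <- function(n_chrom = 3, probes = 2000L, seed = 404) {
  emulate_layout(layout_config(
    probes_per_chrom = stats::setNames(rep.int(probes, n_chrom),
                                       paste0("chr", seq_len(n_chrom)))),
    seed = seed)
}
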