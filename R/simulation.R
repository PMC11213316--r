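#' Simulation configuration
#'
#' The defaults reproduce the benchmark design for a 450K-scale array: 10
#' control and 10 treatment samples; 2,136 of 21,363 candidate promoter
#' regions assigned as true DMRs, half hypermethylated and half
#' hypomethylated; a treatment effect of `delta_beta = 0.2` on the beta scale
#' (use 0.09 for the small-effect setting); beta-values drawn from beta
#' distributions parameterized by their mode, with modes 0.9 (methylated) and
#' 0.1 (unmethylated) for null probes.
#'
#' @param n_control,n_treatment samples per group (default 10 and 10).
#' @param n_regions number of candidate regions used (subsampled from the
#'   layout's candidates when fewer than available; `NULL` = use all).
#' @param n_true number of true-DMR regions.
#' @param delta_beta treatment effect on the beta scale, in (0, 1).
#' @param hyper_fraction fraction of true DMRs that are hypermethylated
#'   (`floor(n_true * hyper_fraction)` regions; the rest hypomethylated).
#' @param mode_methylated,mode_unmethylated beta-distribution modes of the
#'   two methylation statuses of null probes.
#' @param concentration beta-distribution concentration (`shape1 + shape2`),
#'   must exceed 2 for the mode to be defined.
#' @param status_by_region if `TRUE`, all probes of a candidate region share
#'   one methylated/unmethylated status; default `FALSE` (independent
#'   per-probe status, probability 0.5 each).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 10L, n_treatment = 10L,
                       n_regions = 21363L, n_true = 2136L,
                       delta_beta = 0.2, hyper_fraction = 0.5,
                       mode_methylated = 0.9, mode_unmethylated = 0.1,
                       concentration = 10, status_by_region = FALSE) {
  if (n_control < 2 || n_treatment < 2) stop("need at least 2 samples per group")
  if (delta_beta < 0 || delta_beta >= 1)
    stop("delta_beta must be in [0, 1)")   # 0 embeds a pure null

  if (hyper_fraction < 0 || hyper_fraction > 1) stop("hyper_fraction must be in [0, 1]")
  if (mode_methylated <= 0 || mode_methylated >= 1 ||
      mode_unmethylated <= 0 || mode_unmethylated >= 1)
    stop("modes must be in (0, 1)")
  if (concentration <= 2) stop("concentration must exceed 2 (mode undefined otherwise)")
  if (!is.null(n_regions) && n_true > n_regions)
    stop("n_true cannot exceed n_regions")
  structure(list(n_control = as.integer(n_control), n_treatment = as.integer(n_treatment),
                 n_regions = if (is.null(n_regions)) NULL else as.integer(n_regions),
                 n_true = as.integer(n_true),
                 delta_beta = delta_beta, hyper_fraction = hyper_fraction,
                 mode_methylated = mode_methylated, mode_unmethylated = mode_unmethylated,
                 concentration = concentration, status_by_region = isTRUE(status_by_region)),
            class = "sim_config")
}

#' Beta-distribution shapes from mode and concentration
#'
#' For concentration `c = shape1 + shape2 > 2`, the shapes
#' `shape1 = mode * (c - 2) + 1`, `shape2 = (1 - mode) * (c - 2) + 1`
#' give a beta density whose mode, `(shape1 - 1) / (c - 2)`, equals `mode`.
#'
#' @param mode density mode in (0, 1).
#' @param concentration `shape1 + shape2`, > 2.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
beta_from_mode <- function(mode, concentration) {
  if (any(mode <= 0) || any(mode >= 1)) stop("mode must be in (0, 1)")
  if (any(concentration <= 2)) stop("concentration must exceed 2 (mode undefined)")
  c(shape1 = mode * (concentration - 2) + 1,
    shape2 = (1 - mode) * (concentration - 2) + 1)
}

#' Subsample candidate regions
#'
#' @param regions candidate-region data frame (see [candidate_regions()]).
#' @param n_regions number to keep (uniform without replacement); `NULL` or
#'   `>= nrow(regions)` keeps all.
#' @param seed optional integer seed.
#' @return Subset of `regions`, in genomic order.
#' @export
sample_regions <- function(regions, n_regions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_regions) || n_regions >= nrow(regions)) return(regions)
  keep <- sort(sample.int(nrow(regions), n_regions))
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly assign true-DMR labels to candidate regions
#'
#' Selects `n_true` regions uniformly without replacement;
#' `floor(n_true * hyper_fraction)` of them are labeled hypermethylated
#' (methylation higher in treatment), the rest hypomethylated.
#'
#' @param regions candidate-region data frame.
#' @param n_true number of true DMRs (0 gives a pure-null dataset).
#' @param hyper_fraction see [sim_config()].
#' @param seed optional integer seed for reproducibility.
#' @return `regions` with a `label` column in `{"hyper", "hypo", "null"}`.
#' @export
assign_truth <- function(regions, n_true, hyper_fraction = 0.5, seed = NULL) {
  if (n_true > nrow(regions))
    stop("n_true (", n_true, ") exceeds the number of candidate regions (",
         nrow(regions), ")")
  if (!is.null(seed)) set.seed(seed)
  label <- rep("null", nrow(regions))
  if (n_true > 0) {
    pick <- sample.int(nrow(regions), n_true)
    n_hyper <- floor(n_true * hyper_fraction)
    label[pick[seq_len(n_hyper)]] <- "hyper"
    if (n_true > n_hyper) label[pick[(n_hyper + 1):n_true]] <- "hypo"
  }
  regions$label <- label
  regions
}

#' Simulate a methylation-array dataset with known true DMRs
#'
#' Null probes (probes outside true DMRs, including those inside null
#' candidate regions) are assigned a methylation status — methylated or
#' unmethylated — and both groups draw beta-values from the beta distribution
#' at that status's mode. Probes inside a true DMR are all affected: in
#' hypermethylated regions the control group sits at the unmethylated mode
#' and the treatment mode is shifted up by `delta_beta`; hypomethylated
#' regions start from the methylated mode and shift down. Draws are
#' independent across probes and samples.
#'
#' @param layout an [array_layout()] with a `region_id` column (e.g. from
#'   [emulate_layout()]).
#' @param truth labeled regions from [assign_truth()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return List of class `sim_dataset`: `beta` (probes x samples matrix,
#'   strictly inside (0,1)), `truth`, `status` (per-probe status of null
#'   probes), `condition` (per-sample group label), `config`.
#' @export
simulate_dataset <- function(layout, truth, config = sim_config(), seed = NULL) {
  if (!"region_id" %in% names(layout))
    stop("layout needs a region_id column mapping probes to candidate regions")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(layout)
  status <- if (config$status_by_region) {
    # one status per candidate region, independent for background probes
    rid <- layout$region_id
    st <- sample(c("methylated", "unmethylated"), n, replace = TRUE)
    reg_ids <- unique(rid[!is.na(rid)])
    reg_st <- sample(c("methylated", "unmethylated"), length(reg_ids), replace = TRUE)
    st[!is.na(rid)] <- reg_st[match(rid[!is.na(rid)], reg_ids)]
    st
  } else {
    sample(c("methylated", "unmethylated"), n, replace = TRUE)
  }
  mode_ctrl <- ifelse(status == "methylated", config$mode_methylated,
                      config$mode_unmethylated)
  mode_trt <- mode_ctrl
  hyper <- truth$region_id[truth$label == "hyper"]
  hypo <- truth$region_id[truth$label == "hypo"]
  in_hyper <- !is.na(layout$region_id) & layout$region_id %in% hyper
  in_hypo <- !is.na(layout$region_id) & layout$region_id %in% hypo
  mode_ctrl[in_hyper] <- config$mode_unmethylated
  mode_trt[in_hyper] <- config$mode_unmethylated + config$delta_beta
  mode_ctrl[in_hypo] <- config$mode_methylated
  mode_trt[in_hypo] <- config$mode_methylated - config$delta_beta
  if (any(mode_trt <= 0) || any(mode_trt >= 1))
    stop("treatment mode outside (0, 1) after shifting by delta_beta; ",
         "use a baseline mode inside (", config$delta_beta, ", ",
         1 - config$delta_beta, ")")
  cm2 <- config$concentration - 2
  draw <- function(modes, n_samples) {
    sh1 <- modes * cm2 + 1
    sh2 <- (1 - modes) * cm2 + 1
    matrix(stats::rbeta(n * n_samples, sh1, sh2), nrow = n)
  }
  beta <- cbind(draw(mode_ctrl, config$n_control), draw(mode_trt, config$n_treatment))
  rownames(beta) <- layout$probe_id
  colnames(beta) <- c(sprintf("ctrl_%02d", seq_len(config$n_control)),
                      sprintf("trt_%02d", seq_len(config$n_treatment)))
  condition <- rep(c("control", "treatment"), c(config$n_control, config$n_treatment))
  structure(list(beta = beta, truth = truth, status = status,
                 condition = condition, config = config),
            class = "sim_dataset")
}

#' Run simulation replicates through the full detection pipeline
#'
#' For each replicate: re-assign truth labels over a fixed candidate-region
#' set (the array layout is fixed, as for a real array), simulate beta-values,
#' convert to M-values, compute moderated t-statistics once, then smooth,
#' test, and agglomerate under each requested bandwidth mode, and score calls
#' under each overlap criterion. Per-replicate seeds derive deterministically
#' from `seed`.
#'
#' @param layout an [array_layout()] with candidate regions (see
#'   [emulate_layout()]).
#' @param config a [sim_config()].
#' @param n_reps number of replicates (>= 1).
#' @param modes detector variants: subset of `c("faDMR", "aaDMR")`.
#' @param criteria overlap criteria: subset of `c("EO", "AO")`.
#' @param g,alpha,min_probes,fixed_h,window_mult detection parameters, see
#'   [detect_dmrs()].
#' @param seed master integer seed.
#' @return Data frame with one row per replicate x mode x criterion:
#'   confusion counts and metrics (see [evaluate_calls()]), plus `rep` and
#'   `mode` columns.
#' @export
run_replicates <- function(layout, config = sim_config(), n_reps = 1L,
                           modes = c("faDMR", "aaDMR"),
                           criteria = c("EO", "AO"),
                           g = 1000, alpha = 0.05, min_probes = 2,
                           fixed_h = 500, window_mult = 5, seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (n_reps < 1) stop("n_reps must be >= 1")
  regions <- candidate_regions(layout)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps + 1L)
  cand <- sample_regions(regions, config$n_regions, seed = rep_seeds[n_reps + 1L])
  design <- design_info(condition = rep(c("control", "treatment"),
                                        c(config$n_control, config$n_treatment)))
  policies <- lapply(stats::setNames(modes, modes), function(md)
    make_bandwidth_policy(layout, if (md == "faDMR") "fixed" else "adaptive", fixed_h))
  out <- vector("list", n_reps * length(modes))
  k <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    truth <- assign_truth(cand, config$n_true, config$hyper_fraction)
    ds <- simulate_dataset(layout, truth, config)
    m <- beta_to_m(ds$beta)
    st <- site_statistics(m, design)
    base <- data.frame(probe_id = layout$probe_id, chrom = layout$chrom,
                       pos = layout$pos,
                       y = st$y[match(layout$probe_id, st$probe_id)],
                       stringsAsFactors = FALSE)
    for (md in modes) {
      smoothed <- smooth_sites(base, policies[[md]], window_mult = window_mult)
      inferred <- infer_sites(smoothed, alpha = alpha)
      calls <- suppressMessages(
        agglomerate(filter_significant(inferred, alpha), g = g,
                    min_probes = min_probes))
      ev <- evaluate_calls(calls, truth, criteria)
      ev$rep <- r
      ev$mode <- md
      k <- k + 1L
      out[[k]] <- ev
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("rep", "mode", setdiff(names(res), c("rep", "mode")))]
}
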