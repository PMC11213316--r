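test_that("beta shapes from mode and concentration place the density mode", {
  expect_equal(beta_from_mode(0.5, 10), c(shape1 = 5, shape2 = 5))
  sh <- beta_from_mode(0.9, 12)
  expect_equal(unname(sh), c(10, 2))
  expect_equal((sh[["shape1"]] - 1) / (sum(sh) - 2), 0.9)  # argmax of the density
  expect_error(beta_from_mode(0.5, 2), "concentration")
  expect_error(beta_from_mode(1.2, 10), "mode")
  # empirical mode of many draws sits near the requested mode
  set.seed(71)
  x <- rbeta(2e5, sh[["shape1"]], sh[["shape2"]])
  d <- density(x, from = 0.01, to = 0.99)
  expect_lt(abs(d$x[which.max(d$y)] - 0.9), 0.02)
})

test_that("truth assignment splits hyper/hypo as configured and is reproducible", {
  reg <- data.frame(region_id = paste0("r", 1:40), chrom = "chr1",
                    start = seq(1000, by = 5000, length.out = 40),
                    end = seq(2000, by = 5000, length.out = 40))
  t1 <- assign_truth(reg, n_true = 21, hyper_fraction = 0.5, seed = 9)
  expect_equal(sum(t1$label == "hyper"), 10L)   # floor(21 * 0.5)
  expect_equal(sum(t1$label == "hypo"), 11L)
  expect_equal(sum(t1$label == "null"), 19L)
  expect_identical(t1, assign_truth(reg, 21, 0.5, seed = 9))
  t0 <- assign_truth(reg, n_true = 0, seed = 9)
  expect_true(all(t0$label == "null"))
  expect_error(assign_truth(reg, n_true = 41), "exceeds")
})

test_that("simulated datasets carry the configured effects", {
  lay <- small_emulated_layout(n_chrom = 2, probes = 1500L, seed = 81)
  cand <- candidate_regions(lay)
  cfg <- sim_config(n_regions = NULL, n_true = 30, delta_beta = 0.2)
  truth <- assign_truth(cand, 30, seed = 82)
  ds <- simulate_dataset(lay, truth, cfg, seed = 83)
  expect_equal(dim(ds$beta), c(nrow(lay), 20L))
  expect_true(all(ds$beta > 0 & ds$beta < 1))
  ctrl <- ds$beta[, 1:10]; trt <- ds$beta[, 11:20]
  in_hyper <- !is.na(lay$region_id) &
    lay$region_id %in% truth$region_id[truth$label == "hyper"]
  in_hypo <- !is.na(lay$region_id) &
    lay$region_id %in% truth$region_id[truth$label == "hypo"]
  # group-mean difference approximately +/- delta_beta inside true regions
  # (the mode-parameterized beta distribution biases the mean toward 0.5)
  expect_lt(abs(mean(trt[in_hyper, ]) - mean(ctrl[in_hyper, ]) - 0.2), 0.05)
  expect_lt(abs(mean(trt[in_hypo, ]) - mean(ctrl[in_hypo, ]) + 0.2), 0.05)
  expect_gt(mean(trt[in_hyper, ]), mean(ctrl[in_hyper, ]))
  # beta histogram is bimodal: mass near both methylation modes
  expect_gt(mean(ds$beta < 0.3), 0.25)
  expect_gt(mean(ds$beta > 0.7), 0.25)
  # a treatment mode shifted outside (0,1) is rejected with guidance
  bad <- sim_config(n_regions = NULL, n_true = 30, delta_beta = 0.2,
                    mode_unmethylated = 0.85)
  expect_error(simulate_dataset(lay, truth, bad, seed = 83), "baseline")
})

test_that("a zero treatment effect embeds the null exactly", {
  lay <- small_emulated_layout(n_chrom = 1, probes = 800L, seed = 85)
  truth <- assign_truth(candidate_regions(lay), 20, seed = 85)
  cfg <- sim_config(n_regions = NULL, n_true = 20, delta_beta = 0)
  ds <- simulate_dataset(lay, truth, cfg, seed = 86)
  in_true <- !is.na(lay$region_id) &
    lay$region_id %in% truth$region_id[truth$label != "null"]
  d <- mean(ds$beta[in_true, 11:20]) - mean(ds$beta[in_true, 1:10])
  expect_lt(abs(d), 0.02)
})

test_that("per-region methylation status is shared when requested", {
  lay <- small_emulated_layout(n_chrom = 1, probes = 600L, seed = 87)
  truth <- assign_truth(candidate_regions(lay), 0, seed = 87)
  cfg <- sim_config(n_regions = NULL, n_true = 0, status_by_region = TRUE)
  ds <- simulate_dataset(lay, truth, cfg, seed = 88)
  st <- split(ds$status[!is.na(lay$region_id)], lay$region_id[!is.na(lay$region_id)])
  expect_true(all(vapply(st, function(x) length(unique(x)) == 1L, logical(1))))
})

test_that("replicate runs are deterministic and handle the pure null", {
  lay <- small_emulated_layout(n_chrom = 2, probes = 1200L, seed = 91)
  cfg <- sim_config(n_regions = 100, n_true = 10, delta_beta = 0.2)
  r1 <- run_replicates(lay, cfg, n_reps = 2, modes = "aaDMR", seed = 92)
  r2 <- run_replicates(lay, cfg, n_reps = 2, modes = "aaDMR", seed = 92)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2L * 2L)  # reps x criteria
  nullcfg <- sim_config(n_regions = 100, n_true = 0)
  rn <- run_replicates(lay, nullcfg, n_reps = 1, modes = "aaDMR", seed = 93)
  expect_true(all(is.na(rn$recall)))
  expect_true(all(is.finite(rn$FP)))
})

test_that("a reduced benchmark recovers most large-effect DMRs", {
  lay <- emulate_layout(layout_config(
    probes_per_chrom = c(chr1 = 2500, chr2 = 2500)), seed = 95)
  cfg <- sim_config(n_regions = 200, n_true = 20, delta_beta = 0.2)
  res <- run_replicates(lay, cfg, n_reps = 2, seed = 96)
  ao <- res[res$criterion == "AO", ]
  expect_gt(mean(ao$recall), 0.5)
  expect_gt(mean(ao$precision), 0.5)
  expect_true(all(res$TP + res$FN == res$n_true))
})

test_that("sample order within a group does not affect the statistics", {
  lay <- small_emulated_layout(n_chrom = 1, probes = 400L, seed = 97)
  truth <- assign_truth(candidate_regions(lay), 5, seed = 97)
  ds <- simulate_dataset(lay, truth, sim_config(n_regions = NULL, n_true = 5),
                         seed = 98)
  d <- design_info(ds$condition)
  st1 <- site_statistics(beta_to_m(ds$beta), d)
  perm <- c(sample(1:10), sample(11:20))
  st2 <- site_statistics(beta_to_m(ds$beta[, perm]), d)
  expect_equal(st1$moderated_t, st2$moderated_t, tolerance = 1e-10)
})
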