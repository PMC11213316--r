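truth_fix <- data.frame(
  region_id = c("t1", "n1", "n2"),
  chrom = c("chr1", "chr1", "chr2"),
  start = c(10000, 50000, 10000),
  end = c(11200, 51000, 11000),
  label = c("hyper", "null", "null"))

test_that("EO demands exact boundaries, AO any shared base pair", {
  exact <- data.frame(chrom = "chr1", start = 10000, end = 11200)
  ceo <- classify_calls(exact, truth_fix, "EO")
  cao <- classify_calls(exact, truth_fix, "AO")
  expect_equal(c(ceo$TP, ceo$FP), c(1L, 0L))
  expect_equal(c(cao$TP, cao$FP), c(1L, 0L))

  partial <- data.frame(chrom = "chr1", start = 10400, end = 11200)
  expect_equal(classify_calls(partial, truth_fix, "EO")$FP, 1L)
  expect_equal(classify_calls(partial, truth_fix, "AO")$TP, 1L)

  disjoint <- data.frame(chrom = "chr1", start = 20000, end = 21000)
  expect_equal(classify_calls(disjoint, truth_fix, "EO")$FP, 1L)
  expect_equal(classify_calls(disjoint, truth_fix, "AO")$FP, 1L)

  # single shared base pair counts for AO (closed intervals)
  touch <- data.frame(chrom = "chr1", start = 11200, end = 12000)
  expect_equal(classify_calls(touch, truth_fix, "AO")$TP, 1L)

  # empty calls: all true regions are missed
  none <- classify_calls(truth_fix[0, c("chrom", "start", "end")], truth_fix, "AO")
  expect_equal(c(none$TP, none$FP, none$FN, none$TN), c(0L, 0L, 1L, 2L))
})

test_that("confusion margins reproduce the fixed totals", {
  set.seed(61)
  for (rep in 1:5) {
    truth <- data.frame(region_id = paste0("r", 1:30), chrom = "chr1",
                        start = seq(1000, by = 2000, length.out = 30),
                        end = seq(1800, by = 2000, length.out = 30),
                        label = sample(c("hyper", "hypo", "null"), 30, TRUE))
    calls <- data.frame(chrom = "chr1",
                        start = sort(sample.int(60000, 8)))
    calls$end <- calls$start + sample(200:900, 8, TRUE)
    for (cr in c("EO", "AO")) {
      conf <- classify_calls(calls, truth, cr)
      expect_equal(conf$TP + conf$FN, conf$n_true)
      expect_equal(conf$FP + conf$TN, conf$n_null)
      expect_gte(conf$TP, 0L); expect_gte(conf$FN, 0L)
    }
    # a strict-boundary match is also an overlap: EO detects no more than AO
    expect_lte(classify_calls(calls, truth, "EO")$TP,
               classify_calls(calls, truth, "AO")$TP)
    expect_gte(classify_calls(calls, truth, "EO")$FP,
               classify_calls(calls, truth, "AO")$FP)
  }
})

test_that("classification equals the brute-force interval oracle", {
  set.seed(62)
  for (rep in 1:1000) {
    n_t <- sample(1:6, 1); n_c <- sample(0:6, 1)
    starts <- sort(sample(seq(0, 5000, by = 100), n_t))
    truth <- data.frame(region_id = paste0("r", seq_len(n_t)),
                        chrom = sample(c("chrA", "chrB"), n_t, TRUE),
                        start = starts, end = starts + 99,
                        label = "hyper")
    calls <- data.frame(chrom = sample(c("chrA", "chrB"), n_c, TRUE),
                        start = sample(seq(0, 5000, by = 50), n_c))
    calls$end <- calls$start + sample(c(49, 99, 149), n_c, TRUE)
    for (cr in c("EO", "AO")) {
      got <- classify_calls(calls, truth, cr)
      want <- bf_classify(calls, truth, cr)
      expect_equal(got$TP, want$TP)
      expect_equal(got$FP, want$FP)
    }
  }
})

test_that("metrics reproduce benchmark ratios and handle degenerate counts", {
  conf <- structure(list(criterion = "EO", TP = 753L, FP = 992L, FN = 1383L,
                         TN = 18235L, n_true = 2136L, n_null = 19227L,
                         n_calls = 1745L), class = "region_confusion")
  m <- compute_metrics(conf)
  expect_equal(m$precision, 0.4315, tolerance = 1e-3)
  expect_equal(m$recall, 0.3525, tolerance = 1e-3)
  expect_equal(m$type1, 0.0516, tolerance = 1e-3)
  expect_true(m$f1 <= max(m$precision, m$recall))
  # no calls at all: precision and F1 undefined, recall zero
  conf0 <- structure(list(criterion = "AO", TP = 0L, FP = 0L, FN = 10L, TN = 90L,
                          n_true = 10L, n_null = 90L, n_calls = 0L),
                     class = "region_confusion")
  m0 <- compute_metrics(conf0)
  expect_true(is.na(m0$precision) && is.na(m0$f1))
  expect_equal(m0$recall, 0)
  # harmonic-mean fixed point
  confh <- structure(list(criterion = "AO", TP = 5L, FP = 5L, FN = 5L, TN = 85L,
                          n_true = 10L, n_null = 90L, n_calls = 10L),
                     class = "region_confusion")
  expect_equal(compute_metrics(confh)$f1, 0.5)
})

test_that("replicate aggregation summarizes defined metrics only", {
  df <- data.frame(mode = "aaDMR", criterion = "AO",
                   recall = c(0.4, 0.6), precision = c(NA, 0.8),
                   f1 = c(0.5, 0.5), type1 = c(0, 0))
  agg <- suppressMessages(aggregate_replicates(df))
  expect_equal(agg$mean[agg$metric == "recall"], 0.5)
  expect_equal(agg$median[agg$metric == "recall"], 0.5)
  expect_equal(agg$n_used[agg$metric == "precision"], 1L)
  expect_equal(agg$mean[agg$metric == "precision"], 0.8)
  expect_equal(agg$mean[agg$metric == "f1"], agg$median[agg$metric == "f1"])
  expect_message(aggregate_replicates(df), "undefined precision")
})
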